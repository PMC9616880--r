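# Staggered two-fold dilution master-mix manifests: the quantitative ladder.

#' Build a staggered dilution master-mix manifest
#'
#' Divides the panel into groups (of nine by default) and assigns each group
#' to one level of a `fold`-wise dilution series (8 levels by default, i.e.
#' undiluted to 1:128). Equal amounts of each dilution are mixed, so every
#' adaptor's relative concentration is `fold^-group` and its expected read
#' fraction is that concentration over the panel total.
#'
#' @param captor_ids character vector of adaptor ids (or a `captor_panel`);
#'   its length must equal `group_size * n_levels`.
#' @param group_size adaptors per dilution level.
#' @param n_levels number of dilution levels.
#' @param fold dilution factor between consecutive levels (> 1).
#' @param shuffle_seed optional integer; when given, ids are assigned to
#'   groups in a seeded random order instead of input order.
#' @return a `captor_manifest` data.frame with columns `captor_id`, `group`
#'   (0-based level), `relative_concentration`, `expected_fraction`.
#' @export
build_staggered_manifest <- function(captor_ids, group_size = 9,
                                     n_levels = 8, fold = 2,
                                     shuffle_seed = NULL) {
  if (inherits(captor_ids, "captor_panel")) captor_ids <- captor_ids$id
  n <- group_size * n_levels
  if (length(captor_ids) != n) {
    stopf("need exactly group_size * n_levels = %d ids, got %d",
          n, length(captor_ids))
  }
  if (fold <= 1) stopf("fold must be > 1")
  if (anyDuplicated(captor_ids)) stopf("captor ids must be unique")
  if (!is.null(shuffle_seed)) {
    captor_ids <- with_seed(shuffle_seed, sample(captor_ids))
  }
  group <- rep(seq_len(n_levels) - 1L, each = group_size)
  rel <- fold^(-group)
  man <- data.frame(
    captor_id = captor_ids,
    group = group,
    relative_concentration = rel,
    expected_fraction = rel / sum(rel),
    stringsAsFactors = FALSE
  )
  class(man) <- c("captor_manifest", "data.frame")
  man
}

#' Write / read a mixture manifest
#'
#' The TSV stores `captor_id`, `group` and `relative_concentration`;
#' `expected_fraction` is recomputed on read and cross-checked against any
#' stored values.
#'
#' @param manifest a `captor_manifest`.
#' @param path TSV path.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv(manifest, path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- read_tsv(path)
  need <- c("captor_id", "group", "relative_concentration")
  if (!all(need %in% names(x))) {
    stopf("manifest '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  }
  dup <- x$captor_id[duplicated(x$captor_id)]
  if (length(dup)) stopf("manifest '%s': duplicate captor id '%s'", path, dup[1])
  if (any(x$relative_concentration <= 0)) {
    bad <- which(x$relative_concentration <= 0)[1]
    stopf("manifest '%s': non-positive concentration on line %d", path, bad + 1L)
  }
  frac <- x$relative_concentration / sum(x$relative_concentration)
  if (!is.null(x$expected_fraction) &&
      any(abs(x$expected_fraction - frac) > 1e-9)) {
    stopf("manifest '%s': stored expected_fraction is not normalised", path)
  }
  x$expected_fraction <- frac
  class(x) <- c("captor_manifest", "data.frame")
  x
}
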