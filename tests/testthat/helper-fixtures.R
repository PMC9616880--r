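# Shared fixtures (built once per run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

default_panel <- function() {
  fixture("default_panel", function() design_panel(design_config(rng_seed = 11)))
}

small_panel <- function() {
  fixture("small_panel", function() {
    design_panel(design_config(n_adaptors = 8, rng_seed = 5))
  })
}

default_model <- function() {
  fixture("default_model", function() build_context_error_model(rng_seed = 12))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

test_features <- function() {
  fixture("test_features", function() {
    set.seed(32)
    setNames(random_dna(8, 150), paste0("f", 1:8))
  })
}

# a hand-built panel with chosen segments, for constructed-read tests
make_panel <- function(constant5, variable, constant3) {
  p <- data.frame(id = sprintf("CAPTOR_%02d", seq_along(variable)),
                  constant5 = constant5, variable = variable,
                  constant3 = constant3, stringsAsFactors = FALSE)
  p$full_sequence <- paste0(p$constant5, p$variable, p$constant3)
  class(p) <- c("captor_panel", "data.frame")
  p
}

## ---- independent oracles ----

# fitting-alignment distance: minimum global Levenshtein distance (adist)
# between ref and any substring of query, including the empty one
oracle_fit_dist <- function(ref, query) {
  n <- nchar(query)
  best <- nchar(ref)  # align ref against the empty substring
  for (i in seq_len(n)) {
    subs <- substring(query, i, i:n)
    best <- min(best, utils::adist(ref, subs))
  }
  best
}

# brute-force hairpin: enumerate all substrings, look up their reverse
# complements downstream with the loop constraint
oracle_hairpin <- function(seq, min_loop = 3) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0L
  for (i in seq_len(n)) {
    for (L in seq_len(n - i + 1L)) {
      if (L <= best) next
      s <- substring(seq, i, i + L - 1L)
      rcs <- paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
      hits <- gregexpr(rcs, seq, fixed = TRUE)[[1]]
      if (hits[1] == -1) break  # longer extensions of s cannot occur either?
      if (any(hits >= i + L + min_loop)) best <- L
    }
  }
  best
}

# longest common substring of seq with any db record (either strand), by the
# classic dynamic-programming table
oracle_shared_substring <- function(seq, db) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]),
                          collapse = "")
  best <- 0L
  a <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (d in c(db, vapply(db, rc, character(1)))) {
    b <- strsplit(d, "", fixed = TRUE)[[1]]
    prev <- integer(length(b))
    for (i in seq_along(a)) {
      cur <- integer(length(b))
      match_j <- which(b == a[i])
      for (j in match_j) {
        cur[j] <- (if (j > 1) prev[j - 1] else 0L) + 1L
      }
      best <- max(best, cur, best)
      prev <- cur
    }
  }
  best
}

# every string over `alphabet` of length 1..max_len
all_strings <- function(alphabet, max_len) {
  out <- character(0)
  cur <- alphabet
  for (L in seq_len(max_len)) {
    out <- c(out, cur)
    if (L < max_len) cur <- as.vector(outer(cur, alphabet, paste0))
  }
  out
}
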