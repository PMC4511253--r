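# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with the RNG seeded, restoring the caller's RNG state on exit.
# All simulator randomness flows through this so a bundle is a pure function
# of its seed.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Locale-independent (byte-order) sort; all user-visible orderings go through
# radix so results are identical across platforms.
sort_c <- function(x) sort(unique(x), method = "radix")

check_gene_ids <- function(ids, what = "gene id") {
  ids <- as.character(ids)
  if (any(!nzchar(ids))) {
    stop(sprintf("empty %s is not allowed", what), call. = FALSE)
  }
  if (any(grepl("[[:space:]]", ids))) {
    stop(sprintf("%s must not contain whitespace: %s",
                 what, paste(utils::head(ids[grepl("[[:space:]]", ids)], 3),
                             collapse = ", ")), call. = FALSE)
  }
  ids
}

# Canonical unordered pair: byte-lexicographically smaller id first.
canonical_pairs <- function(a, b) {
  lev <- sort(unique(c(a, b)), method = "radix")
  swap <- match(a, lev) > match(b, lev)
  data.frame(gene1 = ifelse(swap, b, a),
             gene2 = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

pair_key <- function(g1, g2) paste(g1, g2, sep = "\t")

# full-precision numeric formatting so write -> read round-trips exactly
num_chr <- function(x) sprintf("%.17g", x)
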