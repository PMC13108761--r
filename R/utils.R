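#' Clinical group labels in disease-severity order
#'
#' @return Character vector `c("HC", "RIS-NC", "RIS-C", "MS")`.
#' @export
group_levels <- function() c("HC", "RIS-NC", "RIS-C", "MS")

abort_config <- function(msg) abort(msg, class = "gmltwin_config_error")
abort_schema <- function(msg) abort(msg, class = "gmltwin_schema_error")
abort_parse <- function(msg) abort(msg, class = "gmltwin_parse_error")

# Evaluate `code` with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched. A NULL seed runs the code on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive n independent stage seeds from one master seed (documented splitting
# rule: a single sample.int() draw from the seeded stream; all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Exactly round(frac * n) TRUE values at seeded-random positions.
exact_bernoulli <- function(n, frac) {
  k <- round(frac * n)
  out <- rep(FALSE, n)
  if (k > 0) out[sample.int(n, k)] <- TRUE
  out
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# subject_id-keyed tibble -> numeric matrix with rownames
tbl_to_matrix <- function(tbl, id_col = "subject_id") {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  m
}

matrix_to_tbl <- function(m, id_col = "subject_id") {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1)
  out
}
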