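# Small fixtures built in code.

# A tiny dense cell_matrix from an explicit matrix.
fixture_cell_matrix <- function(mat, platform = "full_length") {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("g%d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("c%d", seq_len(ncol(mat)))
  }
  cell_matrix(mat, platform = platform)
}

# Annotation for a cell_matrix, one type per cell (recycled).
fixture_annotation <- function(m, cell_type = "type A") {
  data.frame(cell_id = m$cells,
             cell_type = rep_len(cell_type, length(m$cells)),
             tissue = "synthetic", age_months = 3,
             platform = m$platform, stringsAsFactors = FALSE)
}

# Random valid (n, m, k, x) tuples for property tests.
random_hyper_tuples <- function(n_tuples, n_max = 2000, seed = 42) {
  set.seed(seed)
  t(vapply(seq_len(n_tuples), function(i) {
    n <- sample(2:n_max, 1)
    m <- sample(0:n, 1)
    k <- sample(0:n, 1)
    lo <- max(0, m + k - n)
    hi <- min(m, k)
    x <- if (lo == hi) lo else sample(lo:hi, 1)
    c(n = n, m = m, k = k, x = x)
  }, numeric(4)))
}
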