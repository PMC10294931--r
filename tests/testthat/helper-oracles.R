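# Shared fixtures and independent oracles for the test suite.

# Naive reference aggregation: explicit three-pass loop over the node
# table, independent of the matrix arithmetic used by assess().
naive_assess <- function(sheet, h) {
  nodes <- h$nodes
  subj <- colnames(sheet)
  out <- list()
  for (s in subj) {
    vals <- sheet[, s]
    names(vals) <- rownames(sheet)
    for (lvl in c("secondary", "primary", "total")) {
      for (id in nodes$id[nodes$level == lvl]) {
        kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
        acc <- 0
        for (k in kids)
          acc <- acc + nodes$weight[nodes$id == k] * vals[[k]]
        vals[[id]] <- acc
      }
    }
    out[[s]] <- vals
  }
  ids <- c(nodes$id[nodes$level == "secondary"],
           nodes$id[nodes$level == "primary"],
           nodes$id[nodes$level == "total"])
  sapply(out, function(v) unlist(v[ids]))
}

# Perfectly consistent comparison matrix from a positive weight vector.
consistent_matrix <- function(w) {
  m <- outer(w, w, "/")
  diag(m) <- 1
  m
}

# Reciprocal matrix with multiplicative noise on the upper triangle.
perturbed_matrix <- function(w, eps = 0.3) {
  m <- consistent_matrix(w)
  n <- length(w)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[i, j] * exp(stats::runif(1, -eps, eps))
      m[j, i] <- 1 / m[i, j]
    }
  }
  m
}

# Dense eigendecomposition oracle for the dominant eigenpair.
eigen_oracle <- function(m) {
  e <- eigen(m)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  list(lambda = Re(e$values[k]), w = abs(v) / sum(abs(v)))
}

# A small arbitrary 3-level hierarchy (not the bundled model).
toy_hierarchy <- function() {
  nodes <- data.frame(
    id     = c("T", "A", "B", "A1", "A2", "B1", "a", "b", "c", "d"),
    label  = c("total", "A", "B", "A1", "A2", "B1", "a", "b", "c", "d"),
    level  = c("total", "primary", "primary", "secondary", "secondary",
               "secondary", "tertiary", "tertiary", "tertiary",
               "tertiary"),
    parent = c(NA, "T", "T", "A", "A", "B", "A1", "A1", "A2", "B1"),
    weight = c(NA, 0.6, 0.4, 0.7, 0.3, 1, 0.25, 0.75, 1, 1),
    stringsAsFactors = FALSE
  )
  risk_hierarchy(nodes, model_name = "toy")
}
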