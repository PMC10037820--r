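# Independent dense-matrix Markov clustering reference, written from the
# algorithm definition with plain loops and no pruning. Shares only the
# documented conventions with the package implementation: self-loops at
# the column maximum, expansion by squaring, inflation + renormalisation,
# attractor systems merged over exchanged flow, vertices assigned to the
# system with the largest incoming flow (ties to the system holding the
# lexicographically smallest attractor).
mcl_reference <- function(graph, inflation = 2, max_iter = 200,
                          tol = 1e-9) {
  v <- sort(graph$vertices)
  n <- length(v)
  A <- matrix(0, n, n)
  ed <- graph$edges
  for (row in seq_len(nrow(ed))) {
    i <- match(ed$from[row], v)
    j <- match(ed$to[row], v)
    A[i, j] <- ed$weight[row]
    A[j, i] <- ed$weight[row]
  }
  for (j in seq_len(n)) {
    m <- max(A[, j])
    A[j, j] <- if (m > 0) m else 1
  }
  M <- A
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    Mn <- (M %*% M)^inflation
    for (j in seq_len(n)) Mn[, j] <- Mn[, j] / sum(Mn[, j])
    if (max(abs(Mn - M)) < tol) {
      M <- Mn
      break
    }
    M <- Mn
  }
  eps <- 1e-9
  att <- which(diag(M) > eps)
  if (length(att) == 0) att <- seq_len(n)
  # merge attractors that exchange flow, by repeated passes
  sys <- as.list(att)
  repeat {
    merged <- FALSE
    for (i in seq_along(sys)) {
      for (j in seq_along(sys)) {
        if (j <= i || is.null(sys[[i]]) || is.null(sys[[j]])) next
        link <- any(M[sys[[i]], sys[[j]], drop = FALSE] > eps) ||
          any(M[sys[[j]], sys[[i]], drop = FALSE] > eps)
        if (link) {
          sys[[i]] <- c(sys[[i]], sys[[j]])
          sys[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sys <- Filter(Negate(is.null), sys)
  fam <- integer(n)
  for (jx in seq_len(n)) {
    flow <- vapply(sys, function(s) sum(M[s, jx]), numeric(1))
    if (max(flow) <= eps) {
      fam[jx] <- NA_integer_
      next
    }
    cand <- which(flow >= max(flow) - 1e-9)
    if (length(cand) > 1) {
      first_att <- vapply(sys[cand], function(s) v[min(s)], "")
      cand <- cand[order(first_att)][1]
    }
    fam[jx] <- cand
  }
  # orphans become singletons
  next_id <- length(sys)
  for (jx in which(is.na(fam))) {
    next_id <- next_id + 1L
    fam[jx] <- next_id
  }
  data.frame(gene = v, family = fam, stringsAsFactors = FALSE)
}
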