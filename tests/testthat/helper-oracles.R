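# Independent oracles used across the suite. All are deliberately written
# from definitions (dense matrices, recursions), not via the package's own
# computational paths.

# Restricted log-likelihood via the density of orthonormal error contrasts
# K'y ~ N(0, K'VK), shifted by -log|X'X|/2 to the standard (lme4-style)
# REML normalization the package uses.
dense_reml_oracle <- function(V, y, X) {
  n <- length(y)
  p <- ncol(X)
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  S <- crossprod(K, V %*% K)
  ky <- crossprod(K, y)
  as.numeric(-0.5 * (determinant(S, logarithm = TRUE)$modulus +
                       t(ky) %*% solve(S, ky) + (n - p) * log(2 * pi)) -
               0.5 * determinant(crossprod(X), logarithm = TRUE)$modulus)
}

nested_V <- function(theta, sire, dam) {
  Zs <- stats::model.matrix(~ 0 + factor(sire))
  Zd <- stats::model.matrix(~ 0 + factor(dam))
  theta[1] * tcrossprod(Zs) + theta[2] * tcrossprod(Zd) +
    theta[3] * diag(length(sire))
}

biv_V <- function(G, R, Ao) {
  n <- nrow(Ao)
  rbind(cbind(G[1, 1] * Ao + R[1, 1] * diag(n), G[1, 2] * Ao + R[1, 2] * diag(n)),
        cbind(G[1, 2] * Ao + R[1, 2] * diag(n), G[2, 2] * Ao + R[2, 2] * diag(n)))
}

# Additive relationship by memoized kinship recursion (coancestry f;
# A = 2f off-diagonal convention folded in): an implementation independent
# of the tabular loop in the package.
kinship_A_oracle <- function(ped) {
  id <- as.character(ped$individual_id)
  sire <- as.character(ped$sire_id)
  dam <- as.character(ped$dam_id)
  parent <- stats::setNames(Map(c, sire, dam), id)
  memo <- new.env()
  f <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    ia <- match(a, id); ib <- match(b, id)
    val <- if (a == b) {
      pr <- parent[[a]]
      0.5 * (1 + f(pr[1], pr[2]))
    } else {
      # recurse through the younger individual (later in the pedigree)
      if (ia < ib) { tmp <- a; a <- b; b <- tmp }
      pr <- parent[[a]]
      0.5 * (f(pr[1], b) + f(pr[2], b))
    }
    memo[[key]] <- val
    val
  }
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in seq_len(n)) A[i, j] <- 2 * f(id[i], id[j])
  A
}

# quick balanced nested dataset with known components (plain base-R draws)
balanced_nested_data <- function(s, d, k, vs, vd, ve, mu = 10, seed = 1) {
  set.seed(seed)
  sire <- rep(seq_len(s), each = d * k)
  dam <- rep(seq_len(s * d), each = k)
  y <- mu + rnorm(s, 0, sqrt(vs))[sire] + rnorm(s * d, 0, sqrt(vd))[dam] +
    rnorm(s * d * k, 0, sqrt(ve))
  tibble::tibble(sire_id = paste0("s", sire), dam_id = paste0("d", dam), y = y)
}

# three-generation 12-individual pedigree used by the A-matrix tests
pedigree_12 <- function() {
  tibble::tibble(
    individual_id = c("f1", "f2", "f3", "f4",
                      "g1", "g2", "g3", "g4",
                      "h1", "h2", "h3", "h4"),
    sire_id = c(NA, NA, NA, NA,
                "f1", "f1", "f3", "f3",
                "g1", "g1", "g3", "g2"),
    dam_id = c(NA, NA, NA, NA,
               "f2", "f2", "f4", "f2",
               "g4", "g2", "g4", "g4")
  )
}
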