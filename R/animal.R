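#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A from a three-column
#' pedigree using the tabular recursion: individuals are processed in an
#' order where parents precede offspring; for individual `i` with parents
#' `s`, `d`, `A[i,i] = 1 + A[s,d]/2` and `A[i,j] = (A[j,s] + A[j,d])/2` for
#' every earlier `j`. Missing parents contribute zero (unrelated,
#' non-inbred founders). A parent id that never appears as an individual is
#' treated as an unknown founder, with a warning. Cyclic pedigrees are
#' rejected.
#'
#' @param pedigree Tibble/data frame with columns `individual_id`,
#'   `sire_id`, `dam_id` (`NA` for unknown).
#' @return Symmetric matrix with individual ids as dimnames.
#' @export
#' @examples
#' ped <- tibble::tibble(individual_id = c("s", "d1", "d2", "x", "y"),
#'                       sire_id = c(NA, NA, NA, "s", "s"),
#'                       dam_id = c(NA, NA, NA, "d1", "d2"))
#' build_A_matrix(ped)["x", "y"]  # paternal half-sibs: 0.25
build_A_matrix <- function(pedigree) {
  id <- as.character(pedigree$individual_id)
  if (anyDuplicated(id)) stop("duplicated individual ids in pedigree", call. = FALSE)
  sire <- as.character(pedigree$sire_id)
  dam <- as.character(pedigree$dam_id)
  unknown <- function(p) !is.na(p) & !(p %in% id)
  if (any(unknown(sire)) || any(unknown(dam))) {
    warning("parent ids absent from the pedigree treated as unknown founders")
    sire[unknown(sire)] <- NA
    dam[unknown(dam)] <- NA
  }
  n <- length(id)
  pos <- stats::setNames(seq_len(n), id)
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])

  # Kahn-style topological ordering; fails on cycles
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed & (si == 0L | placed[pmax(si, 1L)]) &
                     (di == 0L | placed[pmax(di, 1L)]))
    if (length(ready) == 0) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree contains a cycle (an individual is its own ancestor)",
                         call. = FALSE)

  A <- matrix(0, n, n, dimnames = list(id, id))
  for (r in seq_along(ord)) {
    i <- ord[r]
    s <- si[i]; d <- di[i]
    prev <- ord[seq_len(r - 1L)]
    if (r > 1L) {
      rel <- 0.5 * ((if (s > 0L) A[prev, s] else 0) + (if (d > 0L) A[prev, d] else 0))
      A[prev, i] <- rel
      A[i, prev] <- rel
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

# Align a relationship matrix to a data frame's individual ids and
# eigendecompose once; all animal-model likelihoods work in this basis.
a_eigen <- function(A, ids) {
  ids <- as.character(ids)
  if (!all(ids %in% rownames(A)))
    stop("some individuals are missing from the relationship matrix", call. = FALSE)
  Ao <- A[ids, ids]
  e <- eigen(Ao, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(e$values))
    stop("relationship matrix is not positive semidefinite", call. = FALSE)
  e$values <- pmax(e$values, 0)
  e
}

#' Restricted log-likelihood of a univariate animal model
#'
#' Evaluates the REML log-likelihood under `V = V_A A + V_resid I`, using
#' the eigendecomposition of `A` so each evaluation is linear in the number
#' of records.
#'
#' @param V_A,V_resid Non-negative variance components (`V_resid > 0`).
#' @param y Response vector, ordered as `ids`.
#' @param X Fixed-effect design matrix.
#' @param A Relationship matrix from [build_A_matrix()].
#' @param ids Individual ids matching `y` to rows of `A`.
#' @return Restricted log-likelihood (scalar).
#' @export
reml_loglik_animal <- function(V_A, V_resid, y, X, A, ids = rownames(A)) {
  e <- a_eigen(A, ids)
  animal_ll(c(V_A, V_resid), crossprod(e$vectors, y),
            crossprod(e$vectors, as.matrix(X)), e$values)
}

animal_ll <- function(theta, yt, Xt, lam) {
  V_A <- theta[1]; Ve <- theta[2]
  n <- length(yt); p <- ncol(Xt)
  w <- V_A * lam + Ve
  if (any(w <= 0)) return(-Inf)
  M <- crossprod(Xt / w, Xt)
  cM <- chol(M)
  Xty <- crossprod(Xt, yt / w)
  beta <- backsolve(cM, backsolve(cM, Xty, transpose = TRUE))
  yPy <- sum(yt^2 / w) - drop(crossprod(Xty, beta))
  drop(-0.5 * (sum(log(w)) + 2 * sum(log(diag(cM))) + yPy + (n - p) * log(2 * pi)))
}

#' Fit a univariate animal model by REML
#'
#' Estimates the additive genetic and residual variances of a single trait
#' under `V = V_A A + V_resid I`, profiling the residual variance and
#' maximizing over the ratio `V_A/V_resid` on the log scale.
#'
#' @param data Tibble with an id column, the response and covariates.
#' @param response Response column name.
#' @param A Relationship matrix covering all phenotyped individuals.
#' @param fixed Fixed covariate column names (intercept always included).
#' @param id Name of the id column (default `"female_id"`).
#' @return List of class `animal_fit` with `V_A`, `V_resid`, `beta`,
#'   `beta_cov`, `reml_loglik`, `converged`.
#' @export
fit_univariate_animal_model <- function(data, response, A,
                                        fixed = character(),
                                        id = "female_id") {
  y <- as.numeric(data[[response]])
  X <- cbind(`(Intercept)` = 1, as.matrix(data[fixed]))
  e <- a_eigen(A, data[[id]])
  yt <- drop(crossprod(e$vectors, y))
  Xt <- crossprod(e$vectors, X)
  lam <- e$values
  n <- length(y); p <- ncol(X)

  prof <- function(log_ratio) {
    r <- exp(log_ratio)
    w <- r * lam + 1
    M <- crossprod(Xt / w, Xt)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(1e10)
    Xty <- crossprod(Xt, yt / w)
    beta <- backsolve(cM, backsolve(cM, Xty, transpose = TRUE))
    rss <- sum(yt^2 / w) - drop(crossprod(Xty, beta))
    if (rss <= 0) return(1e10)
    0.5 * ((n - p) * log(rss / (n - p)) + sum(log(w)) + 2 * sum(log(diag(cM))))
  }
  opt <- stats::optimize(prof, c(-30, 15), tol = 1e-10)
  r <- exp(opt$minimum)
  w <- r * lam + 1
  M <- crossprod(Xt / w, Xt)
  Xty <- crossprod(Xt, yt / w)
  beta <- drop(solve(M, Xty))
  rss <- sum(yt^2 / w) - drop(crossprod(Xty, beta))
  Ve <- rss / (n - p)
  V_A <- r * Ve
  if (V_A < 1e-8 * (V_A + Ve)) V_A <- 0
  structure(list(V_A = V_A, V_resid = Ve,
                 beta = stats::setNames(beta, colnames(X)),
                 beta_cov = solve(M) * Ve,
                 reml_loglik = animal_ll(c(V_A, Ve), yt, Xt, lam),
                 n_obs = n, converged = TRUE),
            class = "animal_fit")
}

#' @export
print.animal_fit <- function(x, ...) {
  cat(sprintf("Univariate animal model: V_A = %.4g, V_resid = %.4g, logLik = %.4f\n",
              x$V_A, x$V_resid, x$reml_loglik))
  invisible(x)
}

#' Genetic correlation from additive (co)variances
#'
#' `r_g = cov_A / sqrt(V_A1 * V_A2)`, clipped to `[-1, 1]` with a warning
#' if the raw ratio falls outside.
#'
#' @param cov_A Additive genetic covariance between the traits.
#' @param V_A1,V_A2 Positive additive genetic variances.
#' @return Scalar genetic correlation.
#' @export
genetic_correlation <- function(cov_A, V_A1, V_A2) {
  if (V_A1 <= 0 || V_A2 <= 0)
    stop("additive variances must be positive to define a genetic correlation",
         call. = FALSE)
  r <- cov_A / sqrt(V_A1 * V_A2)
  if (abs(r) > 1) {
    warning("raw genetic correlation ", format(r, digits = 4),
            " outside [-1, 1]; clipped")
    r <- sign(r)
  }
  r
}

# Bivariate REML log-likelihood in the eigenbasis of A: for eigenvalue
# lam_i the 2x2 cross-trait covariance block is lam_i * G + R, so the
# likelihood is a sum of closed-form 2x2 computations.
biv_ll_parts <- function(G, R, yt1, yt2, Xt1, Xt2, lam) {
  s11 <- lam * G[1, 1] + R[1, 1]
  s12 <- lam * G[1, 2] + R[1, 2]
  s22 <- lam * G[2, 2] + R[2, 2]
  det <- s11 * s22 - s12^2
  if (any(det <= 0) || any(s11 <= 0) || any(s22 <= 0)) return(NULL)
  a <- s22 / det; b <- -s12 / det; cc <- s11 / det
  p1 <- ncol(Xt1); p2 <- ncol(Xt2)
  M <- matrix(0, p1 + p2, p1 + p2)
  M[1:p1, 1:p1] <- crossprod(Xt1 * a, Xt1)
  M[1:p1, p1 + 1:p2] <- crossprod(Xt1 * b, Xt2)
  M[p1 + 1:p2, 1:p1] <- t(M[1:p1, p1 + 1:p2])
  M[p1 + 1:p2, p1 + 1:p2] <- crossprod(Xt2 * cc, Xt2)
  v <- c(crossprod(Xt1, a * yt1 + b * yt2), crossprod(Xt2, b * yt1 + cc * yt2))
  q <- sum(a * yt1^2 + 2 * b * yt1 * yt2 + cc * yt2^2)
  list(logdet = sum(log(det)), M = M, v = v, q = q)
}

biv_negll <- function(par, yt1, yt2, Xt1, Xt2, lam) {
  # par: Cholesky factors of G and R: (g11, g21, g22, r11, r21, r22)
  Lg <- matrix(c(par[1], par[2], 0, par[3]), 2, 2)
  Lr <- matrix(c(par[4], par[5], 0, par[6]), 2, 2)
  G <- tcrossprod(Lg); R <- tcrossprod(Lr)
  parts <- biv_ll_parts(G, R, yt1, yt2, Xt1, Xt2, lam)
  if (is.null(parts)) return(1e10)
  cM <- tryCatch(chol(parts$M), error = function(e) NULL)
  if (is.null(cM)) return(1e10)
  beta <- backsolve(cM, backsolve(cM, parts$v, transpose = TRUE))
  yPy <- parts$q - drop(crossprod(parts$v, beta))
  n2 <- 2 * length(lam); p <- length(parts$v)
  0.5 * (parts$logdet + 2 * sum(log(diag(cM))) + yPy + (n2 - p) * log(2 * pi))
}

#' Bivariate REML log-likelihood of an animal model
#'
#' Restricted log-likelihood of two traits on the same individuals under
#' total covariance `G (x) A + R (x) I` (Kronecker structure over traits and
#' individuals).
#'
#' @param G,R 2x2 genetic and residual covariance matrices.
#' @param y1,y2 Trait vectors (same individuals, same order).
#' @param X1,X2 Per-trait fixed-effect design matrices.
#' @param A Relationship matrix.
#' @param ids Individual ids matching the data rows to `A`.
#' @return Restricted log-likelihood (scalar).
#' @export
biv_reml_loglik <- function(G, R, y1, y2, X1, X2, A, ids = rownames(A)) {
  e <- a_eigen(A, ids)
  U <- e$vectors
  parts <- biv_ll_parts(G, R, drop(crossprod(U, y1)), drop(crossprod(U, y2)),
                        crossprod(U, as.matrix(X1)), crossprod(U, as.matrix(X2)),
                        e$values)
  if (is.null(parts)) stop("covariance parameters give a singular model", call. = FALSE)
  cM <- chol(parts$M)
  beta <- backsolve(cM, backsolve(cM, parts$v, transpose = TRUE))
  yPy <- parts$q - drop(crossprod(parts$v, beta))
  n2 <- 2 * length(e$values); p <- length(parts$v)
  drop(-0.5 * (parts$logdet + 2 * sum(log(diag(cM))) + yPy + (n2 - p) * log(2 * pi)))
}

#' Fit a bivariate animal model and estimate the genetic correlation
#'
#' REML estimation of the 2x2 additive genetic covariance matrix `G` and
#' residual covariance `R` for two traits measured on the same individuals,
#' under total covariance `G (x) A + R (x) I`. `G` and `R` are
#' parameterized by their Cholesky factors, so every reported `G` is
#' positive semidefinite by construction. The genetic correlation is
#' `r_g = cov_A / sqrt(V_A1 V_A2)`; its standard error comes from the
#' delta method applied to the inverse curvature (observed information) of
#' the restricted likelihood in the (co)variance parameterization.
#'
#' @param data Tibble with id column, both traits and covariates.
#' @param traits Length-2 character vector of trait column names.
#' @param A Relationship matrix.
#' @param fixed1,fixed2 Fixed covariates per trait.
#' @param id Id column name.
#' @param se Compute the delta-method SE of `r_g`.
#' @param dam_random Also fit a 2x2 dam (common-environment) covariance
#'   `D` with structure `D (x) Z_d Z_d'` (off by default). This loses the
#'   eigenbasis shortcut and evaluates the dense likelihood, so it is
#'   markedly slower; intended for single fits, not simulation studies.
#' @param dam Dam id column, used when `dam_random = TRUE`.
#' @return Object of class `biv_fit` with `V_A1`, `V_A2`, `cov_A`, `V_R1`,
#'   `V_R2`, `cov_R`, `r_g`, `se_r_g`, `reml_loglik`, `converged`.
#' @export
fit_bivariate_animal_model <- function(data, traits, A,
                                       fixed1 = character(),
                                       fixed2 = character(),
                                       id = "female_id", se = TRUE,
                                       dam_random = FALSE, dam = "dam_id") {
  stopifnot(length(traits) == 2)
  y1 <- as.numeric(data[[traits[1]]])
  y2 <- as.numeric(data[[traits[2]]])
  if (anyNA(y1) || anyNA(y2))
    stop("bivariate model requires complete records on both traits", call. = FALSE)
  X1 <- cbind(`(Intercept)` = 1, as.matrix(data[fixed1]))
  X2 <- cbind(`(Intercept)` = 1, as.matrix(data[fixed2]))
  e <- a_eigen(A, data[[id]])
  U <- e$vectors
  yt1 <- drop(crossprod(U, y1)); yt2 <- drop(crossprod(U, y2))
  Xt1 <- crossprod(U, X1); Xt2 <- crossprod(U, X2)
  lam <- e$values

  # starts from univariate fits, with the genetic correlation started at
  # 0 and +/-0.5
  u1 <- fit_univariate_animal_model(data, traits[1], A, fixed = fixed1, id = id)
  u2 <- fit_univariate_animal_model(data, traits[2], A, fixed = fixed2, id = id)
  g1 <- max(u1$V_A, 0.05 * (u1$V_A + u1$V_resid))
  g2 <- max(u2$V_A, 0.05 * (u2$V_A + u2$V_resid))
  start_for <- function(rho) {
    Gs <- matrix(c(g1, rho * sqrt(g1 * g2), rho * sqrt(g1 * g2), g2), 2, 2)
    Rs <- diag(c(max(u1$V_resid, 1e-4), max(u2$V_resid, 1e-4)))
    c(t(chol(Gs))[c(1, 2, 4)], t(chol(Rs))[c(1, 2, 4)])
  }
  best <- NULL
  for (rho in c(0, -0.5, 0.5)) {
    opt <- stats::optim(start_for(rho), biv_negll,
                        yt1 = yt1, yt2 = yt2, Xt1 = Xt1, Xt2 = Xt2, lam = lam,
                        method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  opt <- stats::optim(best$par, biv_negll,
                      yt1 = yt1, yt2 = yt2, Xt1 = Xt1, Xt2 = Xt2, lam = lam,
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  if (opt$value > best$value) opt <- best

  par <- opt$par
  Lg <- matrix(c(par[1], par[2], 0, par[3]), 2, 2)
  Lr <- matrix(c(par[4], par[5], 0, par[6]), 2, 2)
  G <- tcrossprod(Lg); R <- tcrossprod(Lr)
  D <- NULL
  loglik <- -opt$value
  converged <- opt$convergence == 0

  if (dam_random) {
    # dense restricted likelihood over G (x) A + D (x) Zd Zd' + R (x) I;
    # loses the eigenbasis shortcut, so each evaluation is O((2n)^3)
    ids <- as.character(data[[id]])
    Ao <- A[ids, ids]
    DDm <- tcrossprod(stats::model.matrix(~ 0 + factor(data[[dam]])))
    nb <- length(y1)
    In <- diag(nb)
    Xb <- rbind(cbind(X1, matrix(0, nb, ncol(X2))),
                cbind(matrix(0, nb, ncol(X1)), X2))
    yb <- c(y1, y2)
    pb <- ncol(Xb)
    dense_negll_cov <- function(Gm, Rm, Dm) {
      V <- rbind(cbind(Gm[1, 1] * Ao + Dm[1, 1] * DDm + Rm[1, 1] * In,
                       Gm[1, 2] * Ao + Dm[1, 2] * DDm + Rm[1, 2] * In),
                 cbind(Gm[1, 2] * Ao + Dm[1, 2] * DDm + Rm[1, 2] * In,
                       Gm[2, 2] * Ao + Dm[2, 2] * DDm + Rm[2, 2] * In))
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(NA_real_)
      u1 <- backsolve(ch, yb, transpose = TRUE)
      u2 <- backsolve(ch, Xb, transpose = TRUE)
      cM <- tryCatch(chol(crossprod(u2)), error = function(e) NULL)
      if (is.null(cM)) return(NA_real_)
      xty <- crossprod(u2, u1)
      beta <- backsolve(cM, backsolve(cM, xty, transpose = TRUE))
      yPy <- sum(u1^2) - drop(crossprod(xty, beta))
      0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cM))) + yPy +
               (2 * nb - pb) * log(2 * pi))
    }
    dense_negll <- function(p9) {
      Lg <- matrix(c(p9[1], p9[2], 0, p9[3]), 2, 2)
      Lr <- matrix(c(p9[4], p9[5], 0, p9[6]), 2, 2)
      Ld <- matrix(c(p9[7], p9[8], 0, p9[9]), 2, 2)
      v <- dense_negll_cov(tcrossprod(Lg), tcrossprod(Lr), tcrossprod(Ld))
      if (!is.finite(v)) 1e10 else v
    }
    d0 <- sqrt(0.1 * diag(R))
    optd <- stats::optim(c(par, d0[1], 0, d0[2]), dense_negll,
                         method = "Nelder-Mead",
                         control = list(maxit = 20000, reltol = 1e-10))
    p9 <- optd$par
    G <- tcrossprod(matrix(c(p9[1], p9[2], 0, p9[3]), 2, 2))
    R <- tcrossprod(matrix(c(p9[4], p9[5], 0, p9[6]), 2, 2))
    D <- tcrossprod(matrix(c(p9[7], p9[8], 0, p9[9]), 2, 2))
    loglik <- -optd$value
    converged <- optd$convergence == 0
  }

  r_g <- if (G[1, 1] > 0 && G[2, 2] > 0) genetic_correlation(G[1, 2], G[1, 1], G[2, 2]) else NA_real_

  se_r_g <- NA_real_
  if (se && is.finite(r_g) && G[1, 1] > 0 && G[2, 2] > 0) {
    # observed information in the (co)variance parameterization
    nll_theta <- function(th) {
      Gt <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
      Rt <- matrix(c(th[4], th[5], th[5], th[6]), 2, 2)
      if (dam_random) {
        Dt <- matrix(c(th[7], th[8], th[8], th[9]), 2, 2)
        v <- dense_negll_cov(Gt, Rt, Dt)
        return(if (is.finite(v)) v - 0.5 * (2 * length(lam) - ncol(Xt1) -
                                              ncol(Xt2)) * log(2 * pi) else NA_real_)
      }
      parts <- biv_ll_parts(Gt, Rt, yt1, yt2, Xt1, Xt2, lam)
      if (is.null(parts)) return(NA_real_)
      cM <- tryCatch(chol(parts$M), error = function(e) NULL)
      if (is.null(cM)) return(NA_real_)
      beta <- backsolve(cM, backsolve(cM, parts$v, transpose = TRUE))
      yPy <- parts$q - drop(crossprod(parts$v, beta))
      0.5 * (parts$logdet + 2 * sum(log(diag(cM))) + yPy)
    }
    th <- c(G[1, 1], G[1, 2], G[2, 2], R[1, 1], R[1, 2], R[2, 2])
    if (dam_random) th <- c(th, D[1, 1], D[1, 2], D[2, 2])
    H <- num_hessian(nll_theta, th)
    cov_th <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_th) && all(is.finite(cov_th))) {
      gr <- c(-r_g / (2 * G[1, 1]), 1 / sqrt(G[1, 1] * G[2, 2]),
              -r_g / (2 * G[2, 2]), rep(0, length(th) - 3))
      v <- drop(crossprod(gr, cov_th %*% gr))
      if (is.finite(v) && v >= 0) se_r_g <- sqrt(v)
    }
  }

  structure(list(V_A1 = G[1, 1], V_A2 = G[2, 2], cov_A = G[1, 2],
                 V_R1 = R[1, 1], V_R2 = R[2, 2], cov_R = R[1, 2],
                 G = G, R = R, D = D, r_g = r_g, se_r_g = se_r_g,
                 reml_loglik = loglik,
                 traits = traits, n_obs = length(lam),
                 converged = converged),
            class = "biv_fit")
}

# central-difference Hessian of f at x
num_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x) * rel_step, 1e-6)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.biv_fit <- function(x, ...) {
  cat(sprintf("Bivariate animal model: %s ~ %s (n = %d)\n",
              x$traits[1], x$traits[2], x$n_obs))
  cat(sprintf("  V_A = (%.4g, %.4g), cov_A = %.4g\n", x$V_A1, x$V_A2, x$cov_A))
  cat(sprintf("  r_g = %.3f (SE %.3f)%s\n", x$r_g, x$se_r_g,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @rdname fit_bivariate_animal_model
#' @param x A `biv_fit` object.
#' @param ... Unused.
#' @export
tidy.biv_fit <- function(x, ...) {
  tibble::tibble(
    term = c("V_A1", "V_A2", "cov_A", "V_R1", "V_R2", "cov_R", "r_g"),
    estimate = c(x$V_A1, x$V_A2, x$cov_A, x$V_R1, x$V_R2, x$cov_R, x$r_g),
    std.error = c(rep(NA_real_, 6), x$se_r_g))
}

#' @rdname fit_bivariate_animal_model
#' @export
glance.biv_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, r_g = x$r_g, se_r_g = x$se_r_g,
                 logLik = x$reml_loglik, converged = x$converged)
}
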