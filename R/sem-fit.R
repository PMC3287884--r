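# ML covariance-structure estimation internals.
#
# Optimization runs in a preconditioned space: free variances (diagonals of
# Theta, Psi, Phi) on the log scale (positive and scale-free), and every
# other free parameter divided by its standardizing scale (products of the
# connected variables' standard deviations), so the surface is comparably
# conditioned whatever the raw units of the data. Gradients of F_ML are
# analytic: dF = tr[(Sigma^-1 - Sigma^-1 S Sigma^-1) dSigma].

free_par_info <- function(model) {
  pt <- model$partable[model$partable$free, , drop = FALSE]
  list(pt = pt,
       logscale = pt$mat %in% c("theta", "psi", "phi") & pt$row == pt$col)
}

# per-parameter scale of the non-variance coordinates, from observed sds
# (latent scale taken from its marker indicator)
free_par_scale <- function(model, S) {
  sdv <- sqrt(diag(S))
  sd_y <- sdv[model$yvars]
  sd_x <- sdv[model$xvars]
  sd_l <- vapply(seq_along(model$lvars), function(k) {
    lv <- model$lvars[k]
    marker <- if (model$pseudo[k]) lv else model$latents[[lv]][1L]
    unname(sdv[marker])
  }, numeric(1))
  fp <- free_par_info(model)
  s <- rep(1, nrow(fp$pt))
  for (r in seq_len(nrow(fp$pt))) {
    row <- fp$pt[r, ]; i <- row$row; j <- row$col
    s[r] <- switch(row$mat,
      lambda = sd_y[i] / sd_l[j],
      beta   = sd_l[i] / sd_l[j],
      gamma  = sd_l[i] / sd_x[j],
      psi    = sd_l[i] * sd_l[j],
      theta  = sd_y[i] * sd_y[j],
      phi    = sd_x[i] * sd_x[j])
  }
  s[fp$logscale] <- 1
  s
}

to_raw <- function(xi, logscale, scale = 1) {
  th <- xi * scale
  th[logscale] <- exp(xi[logscale])
  th
}
to_xi <- function(th, logscale, scale = 1) {
  xi <- th / scale
  xi[logscale] <- log(th[logscale])
  xi
}

sem_start_values <- function(model, S) {
  pt <- model$partable
  fp <- free_par_info(model)
  yv <- model$yvars; xv <- model$xvars
  s_of <- function(a, b) S[a, b]
  markers <- character(length(model$lvars))
  names(markers) <- model$lvars
  for (k in seq_along(model$lvars)) {
    lv <- model$lvars[k]
    markers[k] <- if (model$pseudo[k]) lv else model$latents[[lv]][1L]
  }
  th <- numeric(nrow(fp$pt))
  for (r in seq_len(nrow(fp$pt))) {
    row <- fp$pt[r, ]
    th[r] <- switch(row$mat,
      lambda = {
        lv <- model$lvars[row$col]; ym <- markers[lv]; yj <- yv[row$row]
        if (model$std_latent && !model$endo[lv] && !model$pseudo[lv])
          s_of(yj, ym) / sqrt(max(s_of(ym, ym), 1e-8))
        else s_of(yj, ym) / max(s_of(ym, ym), 1e-8)
      },
      beta = 0,
      gamma = 0,
      psi = if (row$row == row$col) 0.5 * max(S[markers[row$row], markers[row$row]], 1e-4) else 0,
      theta = if (row$row == row$col) 0.5 * max(S[yv[row$row], yv[row$row]], 1e-4) else 0,
      phi = S[xv[row$row], xv[row$col]])
  }
  # keep loading starts sane for near-degenerate markers
  lam <- fp$pt$mat == "lambda"
  th[lam] <- pmax(pmin(th[lam], 5), -5)
  th[lam][!is.finite(th[lam])] <- 0.7
  # variance starts strictly positive
  vv <- fp$logscale
  th[vv] <- pmax(th[vv], 1e-4)
  th
}

# E-blocks of the gradient kernel at Sigma
sem_grad_raw <- function(model, mats, sig, S) {
  P <- nrow(sig$Sigma)
  p <- length(model$yvars); q <- length(model$xvars)
  chS <- chol(sig$Sigma)
  Sinv <- chol2inv(chS)
  E <- Sinv - Sinv %*% S %*% Sinv
  E <- (E + t(E)) / 2
  iy <- seq_len(p); ix <- if (q) p + seq_len(q) else integer(0)
  Eyy <- E[iy, iy, drop = FALSE]
  Eyx <- if (q) E[iy, ix, drop = FALSE] else matrix(0, p, 0)
  Exx <- if (q) E[ix, ix, drop = FALSE] else matrix(0, 0, 0)
  LA <- sig$LA; A <- sig$A; C <- sig$C_eta
  L <- mats$L; G <- mats$G; Ph <- mats$Ph
  AGP <- if (q) A %*% G %*% Ph else matrix(0, ncol(L), 0)   # m x q
  M1 <- 2 * (Eyy %*% L %*% C + (if (q) Eyx %*% t(AGP) else 0))
  T1 <- C %*% t(L) %*% Eyy %*% LA
  T2 <- if (q) AGP %*% t(Eyx) %*% LA else 0
  M2 <- 2 * t(T1 + T2)                                      # m x m, grad for B[i,j]
  M4 <- t(LA) %*% Eyy %*% LA                                # psi kernel
  if (q) {
    U1 <- Ph %*% t(G) %*% M4                                # q x m
    U2 <- Ph %*% t(Eyx) %*% LA
    MG <- 2 * t(U1 + U2)                                    # m x q, grad for Gamma
    N1 <- t(G) %*% M4 %*% G
    N2 <- t(LA %*% G) %*% Eyx
    Qx <- N1 + N2 + t(N2) + Exx                             # phi kernel
  } else { MG <- NULL; Qx <- NULL }
  fp <- free_par_info(model)
  g <- numeric(nrow(fp$pt))
  for (r in seq_len(nrow(fp$pt))) {
    row <- fp$pt[r, ]; i <- row$row; j <- row$col
    g[r] <- switch(row$mat,
      lambda = M1[i, j],
      beta   = M2[i, j],
      gamma  = MG[i, j],
      psi    = if (i == j) M4[i, i] else 2 * M4[i, j],
      theta  = if (i == j) Eyy[i, i] else 2 * Eyy[i, j],
      phi    = if (i == j) Qx[i, i] else 2 * Qx[i, j])
  }
  g
}

sem_optimize <- function(model, S, control) {
  fp <- free_par_info(model)
  pscale <- free_par_scale(model, S)
  start <- control$start %||% sem_start_values(model, S)
  if (length(start) != nrow(fp$pt)) stopf("start vector has wrong length")
  # keep start variances usefully inside the parameter space
  vfloor <- 1e-4 * mean(diag(S))
  start[fp$logscale] <- pmax(start[fp$logscale], vfloor)
  xi0 <- to_xi(start, fp$logscale, pscale)
  # log-variances bounded below: a Heywood direction stops at a tiny
  # positive value (flagged inadmissible) instead of sliding to -Inf
  lower <- rep(-Inf, length(xi0))
  lower[fp$logscale] <- log(1e-10 * max(diag(S)))
  P <- nrow(S)
  big <- 1e12

  objective <- function(xi) {
    th <- to_raw(xi, fp$logscale, pscale)
    mats <- model_matrices(model, th)
    sig <- tryCatch(sem_sigma(mats), error = function(e) NULL)
    if (is.null(sig)) return(big)
    ch <- tryCatch(chol(sig$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(big)
    ld <- 2 * sum(log(diag(ch)))
    val <- ld + sum(S * chol2inv(ch)) - control$ldS - P
    if (!is.finite(val)) big else val
  }
  gradient <- function(xi) {
    th <- to_raw(xi, fp$logscale, pscale)
    mats <- model_matrices(model, th)
    sig <- tryCatch(sem_sigma(mats), error = function(e) NULL)
    ok <- !is.null(sig) &&
      !inherits(tryCatch(chol(sig$Sigma), error = function(e) e), "error")
    if (!ok) return(rep(0, length(xi)))
    g <- sem_grad_raw(model, mats, sig, S) * pscale
    g[fp$logscale] <- g[fp$logscale] * th[fp$logscale]   # chain rule for log-variances
    g
  }

  opt <- stats::nlminb(xi0, objective, gradient = gradient, lower = lower,
                       control = list(iter.max = control$max_iter,
                                      eval.max = 4L * control$max_iter,
                                      rel.tol = 1e-12))
  at_bound <- opt$par <= lower + 1e-9
  grad_free <- function(par) {
    g <- gradient(par)
    g[par <= lower + 1e-9 & g > 0] <- 0   # boundary-active coordinates
    g
  }
  gn <- max(abs(grad_free(opt$par)))
  # polish: alternate BFGS and nlminb restarts until the gradient tolerance
  # holds or progress stalls
  round <- 0L
  while (gn > control$gr_tol && round < 4L) {
    round <- round + 1L
    pol <- if (round %% 2L == 1L)
      tryCatch(stats::optim(opt$par, objective, gradient, method = "L-BFGS-B",
                            lower = lower,
                            control = list(maxit = control$max_iter,
                                           factr = 10)),
               error = function(e) list(par = opt$par, value = opt$objective))
    else {
      nl <- stats::nlminb(opt$par, objective, gradient = gradient,
                          lower = lower,
                          control = list(iter.max = control$max_iter,
                                         rel.tol = 1e-13))
      list(par = nl$par, value = nl$objective)
    }
    if (pol$value <= opt$objective + 1e-12) {
      gn_new <- max(abs(grad_free(pol$par)))
      no_better <- gn_new >= gn && pol$value >= opt$objective - 1e-14
      opt$par <- pol$par; opt$objective <- pol$value; gn <- gn_new
      if (no_better) break
    } else break
  }
  theta <- to_raw(opt$par, fp$logscale, pscale)
  # Newton refinement: near the optimum the Hessian of F is twice the
  # expected information, giving quadratic convergence below the
  # quasi-Newton precision floor
  newton <- 0L
  while (gn > control$gr_tol && newton < 5L) {
    newton <- newton + 1L
    step_ok <- tryCatch({
      mats <- model_matrices(model, theta)
      sig <- sem_sigma(mats)
      g_raw <- sem_grad_raw(model, mats, sig, S)
      H <- 2 * sem_information(sig$Sigma, sem_dsigma(model, mats, sig))
      delta <- solve(H + diag(1e-10, nrow(H)), g_raw)
      step <- 1
      repeat {
        cand <- theta - step * delta
        if (all(cand[fp$logscale] > 0)) {
          xi_c <- to_xi(cand, fp$logscale, pscale)
          if (objective(xi_c) <= opt$objective + 1e-10) break
        }
        step <- step / 2
        if (step < 1e-4) break
      }
      if (step >= 1e-4) {
        theta <- theta - step * delta
        xi_c <- to_xi(theta, fp$logscale, pscale)
        opt$par <- xi_c
        opt$objective <- objective(xi_c)
        gn_new <- max(abs(grad_free(xi_c)))
        improved <- gn_new < gn
        gn <- gn_new
        improved
      } else FALSE
    }, error = function(e) FALSE)
    if (!isTRUE(step_ok)) break
  }
  list(theta = theta, value = opt$objective, grad_norm = gn,
       converged = is.finite(opt$objective) && gn < control$gr_tol,
       iterations = opt$iterations %||% NA_integer_)
}

# per-free-parameter dSigma matrices at theta (list of P x P matrices)
sem_dsigma <- function(model, mats, sig) {
  p <- length(model$yvars); q <- length(model$xvars); m <- length(model$lvars)
  P <- p + q
  L <- mats$L; G <- mats$G; Ph <- mats$Ph
  A <- sig$A; LA <- sig$LA; C <- sig$C_eta; W <- sig$W
  AGP <- if (q) A %*% G %*% Ph else NULL
  GP <- if (q) G %*% Ph else NULL
  fp <- free_par_info(model)
  out <- vector("list", nrow(fp$pt))
  Esym <- function(n, i, j) { M <- matrix(0, n, n); M[i, j] <- M[j, i] <- 1; M }
  for (r in seq_len(nrow(fp$pt))) {
    row <- fp$pt[r, ]; i <- row$row; j <- row$col
    dyy <- matrix(0, p, p); dyx <- if (q) matrix(0, p, q) else NULL; dxx <- NULL
    if (row$mat == "lambda") {
      J <- matrix(0, p, m); J[i, j] <- 1
      t1 <- J %*% C %*% t(L)
      dyy <- t1 + t(t1)
      if (q) dyx <- J %*% AGP
    } else if (row$mat == "beta") {
      Jb <- matrix(0, m, m); Jb[i, j] <- 1
      dA <- A %*% Jb %*% A
      t1 <- L %*% dA %*% W %*% t(A) %*% t(L)
      dyy <- t1 + t(t1)
      if (q) dyx <- L %*% dA %*% GP
    } else if (row$mat == "gamma") {
      Jg <- matrix(0, m, q); Jg[i, j] <- 1
      dW <- Jg %*% t(GP)
      dW <- dW + t(dW)
      dyy <- LA %*% dW %*% t(LA)
      dyx <- LA %*% Jg %*% Ph
    } else if (row$mat == "psi") {
      dyy <- LA %*% Esym(m, i, j) %*% t(LA)
    } else if (row$mat == "theta") {
      dyy <- Esym(p, i, j)
    } else if (row$mat == "phi") {
      Ex <- Esym(q, i, j)
      dyy <- LA %*% G %*% Ex %*% t(G) %*% t(LA)
      dyx <- LA %*% G %*% Ex
      dxx <- Ex
    }
    D <- matrix(0, P, P)
    D[seq_len(p), seq_len(p)] <- dyy
    if (q) {
      if (!is.null(dyx)) {
        D[seq_len(p), p + seq_len(q)] <- dyx
        D[p + seq_len(q), seq_len(p)] <- t(dyx)
      }
      if (!is.null(dxx)) D[p + seq_len(q), p + seq_len(q)] <- dxx
    }
    out[[r]] <- D
  }
  out
}

# expected information I_ab = 0.5 tr(Sigma^-1 dSig_a Sigma^-1 dSig_b)
sem_information <- function(Sigma, dsig) {
  Sinv <- chol2inv(chol(Sigma))
  K <- lapply(dsig, function(D) Sinv %*% D)
  nf <- length(dsig)
  info <- matrix(0, nf, nf)
  for (a in seq_len(nf)) for (b in a:nf) {
    v <- 0.5 * sum(K[[a]] * t(K[[b]]))
    info[a, b] <- info[b, a] <- v
  }
  info
}

# Delta matrix: columns vech(dSigma_a)
sem_delta <- function(dsig) {
  if (!length(dsig)) return(matrix(0, 0, 0))
  do.call(cbind, lapply(dsig, vech))
}
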