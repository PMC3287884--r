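#' Parse a structural equation model specification
#'
#' The plain-text grammar (one statement per line, `#` comments):
#' \describe{
#'   \item{`latent <name> = <ind> [+ <ind> ...]`}{measurement model: the
#'     latent's indicators, in order. By default the first indicator is the
#'     marker (loading fixed to 1).}
#'   \item{`path <from> -> <to>`}{structural or covariate path. A `to` that
#'     is an observed variable is treated as an endogenous observed outcome
#'     (internally a single-indicator latent with zero measurement error);
#'     an observed `from` that is never a target or indicator is an
#'     exogenous covariate.}
#'   \item{`covary <a> <b>`}{frees a residual covariance: between two
#'     indicators (measurement residuals), two latents (disturbances /
#'     latent covariance), or two exogenous covariates. Names not seen
#'     elsewhere are registered as exogenous observed variables, so a model
#'     of only `covary` lines is the saturated model.}
#'   \item{`fix <label> = <value>`}{fixes a parameter; labels are
#'     `L=~ind` (loading), `from->to` (path), `a~~b` (variance/covariance).}
#'   \item{`std_latent`}{identify latents by fixing exogenous latent
#'     variances to 1 (all loadings free) instead of marker loadings.}
#' }
#'
#' Exogenous covariates are modeled jointly with the outcomes (their
#' covariance block is saturated and free). Exogenous latents are
#' uncorrelated unless `covary` says otherwise.
#'
#' @param text character scalar (newline separated) or vector of lines, or a
#'   path to a `.sem` file.
#' @return An object of class `sem_model`: observed/latent variable lists
#'   and a parameter table (`partable`).
#' @export
sem_model <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty model specification")

  latents <- list(); paths <- list(); covaries <- list(); fixes <- list()
  std_latent <- FALSE
  for (ln in lines) {
    if (ln == "std_latent") { std_latent <- TRUE; next }
    if (grepl("^latent\\s", ln)) {
      m <- regmatches(ln, regexec("^latent\\s+(\\S+)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) != 3L) stopf("cannot parse latent line: '%s'", ln)
      inds <- trimws(strsplit(m[3], "+", fixed = TRUE)[[1]])
      if (any(!nzchar(inds))) stopf("empty indicator in: '%s'", ln)
      if (anyDuplicated(inds)) stopf("duplicate indicator in: '%s'", ln)
      if (m[2] %in% names(latents)) stopf("duplicate latent declaration: '%s'", m[2])
      latents[[m[2]]] <- inds
    } else if (grepl("^path\\s", ln)) {
      m <- regmatches(ln, regexec("^path\\s+(\\S+)\\s*->\\s*(\\S+)\\s*$", ln))[[1]]
      if (length(m) != 3L) stopf("cannot parse path line: '%s'", ln)
      paths[[length(paths) + 1L]] <- c(from = m[2], to = m[3])
    } else if (grepl("^covary\\s", ln)) {
      m <- regmatches(ln, regexec("^covary\\s+(\\S+)\\s+(\\S+)\\s*$", ln))[[1]]
      if (length(m) != 3L) stopf("cannot parse covary line: '%s'", ln)
      if (m[2] == m[3]) stopf("covary needs two distinct variables: '%s'", ln)
      covaries[[length(covaries) + 1L]] <- c(a = m[2], b = m[3])
    } else if (grepl("^fix\\s", ln)) {
      m <- regmatches(ln, regexec("^fix\\s+(\\S+)\\s*=\\s*(\\S+)\\s*$", ln))[[1]]
      if (length(m) != 3L) stopf("cannot parse fix line: '%s'", ln)
      v <- suppressWarnings(as.numeric(m[3]))
      if (is.na(v)) stopf("fix value must be numeric: '%s'", ln)
      fixes[[length(fixes) + 1L]] <- list(label = m[2], value = v)
    } else stopf("unrecognized model statement: '%s'", ln)
  }

  lat_names <- names(latents)
  indicators <- unique(unlist(latents, use.names = FALSE))
  if (length(bad <- intersect(lat_names, indicators)))
    stopf("name used as both latent and indicator: %s", paste(bad, collapse = ", "))
  p_from <- vapply(paths, `[[`, "", "from")
  p_to <- vapply(paths, `[[`, "", "to")
  if (any(dup <- duplicated(paste(p_from, p_to))))
    stopf("duplicate path declaration: %s",
          paste(unique(paste0(p_from[dup], "->", p_to[dup])), collapse = ", "))
  obs_targets <- setdiff(p_to, lat_names)
  if (length(bad <- intersect(obs_targets, indicators)))
    stopf("an indicator cannot also be a path target: %s", paste(bad, collapse = ", "))
  obs_sources <- setdiff(p_from, c(lat_names, obs_targets))
  if (length(bad <- intersect(obs_sources, indicators)))
    stopf("an indicator cannot also be a path source: %s", paste(bad, collapse = ", "))
  cov_names <- unique(unlist(covaries, use.names = FALSE))
  known <- c(lat_names, indicators, obs_targets, obs_sources)
  xvars <- unique(c(obs_sources, setdiff(cov_names, known)))

  yvars <- c(indicators, obs_targets)              # modeled outcomes, model order
  lvars <- c(lat_names, obs_targets)               # user latents then pseudo-latents
  pseudo <- c(rep(FALSE, length(lat_names)), rep(TRUE, length(obs_targets)))
  names(pseudo) <- lvars
  if (!length(yvars) && !length(xvars))
    stopf("model declares no observed variables")

  p <- length(yvars); m <- length(lvars); q <- length(xvars)
  endo <- stats::setNames(rep(FALSE, m), lvars)    # latent receives any path?
  for (pa in paths) endo[pa["to"]] <- TRUE

  rows <- list()
  add <- function(mat, i, j, free, value, label, class) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mat = mat, row = i, col = j, free = free,
      value = ifelse(free, NA_real_, value), label = label, class = class,
      stringsAsFactors = FALSE)
  }
  # measurement model
  for (k in seq_along(lat_names)) {
    inds <- latents[[k]]
    for (jj in seq_along(inds)) {
      i <- match(inds[jj], yvars)
      # std_latent identification only applies to exogenous latents; an
      # endogenous latent's scale is still set by its marker loading
      marker <- (jj == 1L) && (!std_latent || endo[lat_names[k]])
      add("lambda", i, k, free = !marker, value = 1,
          label = paste0(lat_names[k], "=~", inds[jj]), class = "loading")
    }
  }
  for (k in seq_along(obs_targets)) {
    i <- match(obs_targets[k], yvars)
    add("lambda", i, length(lat_names) + k, free = FALSE, value = 1,
        label = paste0(".", obs_targets[k], "=~", obs_targets[k]), class = "loading_fixed")
  }
  # structural paths
  for (pa in paths) {
    to_i <- match(pa["to"], lvars)
    if (is.na(to_i)) stopf("path target '%s' could not be resolved", pa["to"])
    if (pa["from"] %in% lvars) {
      from_i <- match(pa["from"], lvars)
      if (from_i == to_i) stopf("self-path '%s -> %s' not allowed", pa["from"], pa["to"])
      add("beta", to_i, from_i, free = TRUE, value = NA,
          label = paste0(pa["from"], "->", pa["to"]), class = "path")
    } else {
      from_i <- match(pa["from"], xvars)
      add("gamma", to_i, from_i, free = TRUE, value = NA,
          label = paste0(pa["from"], "->", pa["to"]), class = "path")
    }
  }
  # latent (co)variances: Psi
  for (k in seq_len(m)) {
    fixed_one <- std_latent && !pseudo[k] && !endo[k]
    add("psi", k, k, free = !fixed_one, value = 1,
        label = paste0(lvars[k], "~~", lvars[k]),
        class = if (endo[k] || pseudo[k]) "disturbance" else "lvariance")
  }
  # measurement residuals: Theta (pseudo rows fixed to zero)
  for (i in seq_len(p)) {
    is_pseudo_row <- yvars[i] %in% obs_targets
    add("theta", i, i, free = !is_pseudo_row, value = 0,
        label = if (is_pseudo_row) paste0(".eps.", yvars[i])
                else paste0(yvars[i], "~~", yvars[i]),
        class = if (is_pseudo_row) "resid_fixed" else "residual")
  }
  # covariances from 'covary'
  for (cv in covaries) {
    a <- cv["a"]; b <- cv["b"]
    if (a %in% lvars && b %in% lvars) {
      i <- match(a, lvars); j <- match(b, lvars)
      add("psi", max(i, j), min(i, j), free = TRUE, value = NA,
          label = paste0(lvars[min(i, j)], "~~", lvars[max(i, j)]),
          class = "lcovariance")
    } else if (a %in% yvars && b %in% yvars) {
      i <- match(a, yvars); j <- match(b, yvars)
      add("theta", max(i, j), min(i, j), free = TRUE, value = NA,
          label = paste0(yvars[min(i, j)], "~~", yvars[max(i, j)]),
          class = "rcovariance")
    } else if (a %in% xvars && b %in% xvars) {
      # Phi is saturated and free anyway; nothing to add
    } else {
      stopf("covary between '%s' and '%s' is not supported (mixed kinds)", a, b)
    }
  }
  # exogenous covariate block: Phi saturated free
  for (j in seq_len(q)) for (i in j:q) {
    add("phi", i, j, free = TRUE, value = NA,
        label = paste0(xvars[j], "~~", xvars[i]),
        class = if (i == j) "xvariance" else "xcovariance")
  }

  partable <- do.call(rbind, rows)
  if (anyDuplicated(partable[, c("mat", "row", "col")]))
    stopf("duplicate parameter declarations (check covary/path lines)")
  # apply fixes
  for (fx in fixes) {
    hit <- which(partable$label == fx$label)
    hit <- hit[partable$class[hit] != "resid_fixed"]
    if (!length(hit)) stopf("fix refers to unknown parameter '%s'", fx$label)
    partable$free[hit] <- FALSE
    partable$value[hit] <- fx$value
  }
  partable$id <- seq_len(nrow(partable))
  free_id <- integer(nrow(partable))
  free_id[partable$free] <- seq_len(sum(partable$free))
  partable$free_id <- free_id

  structure(list(yvars = yvars, xvars = xvars, lvars = lvars,
                 pseudo = pseudo, endo = endo, latents = latents,
                 partable = partable, std_latent = std_latent,
                 text = paste(lines, collapse = "\n")),
            class = "sem_model")
}

#' @export
print.sem_model <- function(x, ...) {
  cat("SEM model specification\n")
  cat(sprintf("  observed outcomes (y): %d, exogenous covariates (x): %d\n",
              length(x$yvars), length(x$xvars)))
  cat(sprintf("  latent variables: %d (%d observed-outcome pseudo-latents)\n",
              length(x$lvars), sum(x$pseudo)))
  cat(sprintf("  free parameters: %d, fixed: %d\n",
              sum(x$partable$free), sum(!x$partable$free)))
  invisible(x)
}

# number of free parameters
n_free <- function(model) sum(model$partable$free)

# build the model matrices from a free-parameter vector (raw scale)
model_matrices <- function(model, theta) {
  p <- length(model$yvars); m <- length(model$lvars); q <- length(model$xvars)
  L <- matrix(0, p, m, dimnames = list(model$yvars, model$lvars))
  B <- matrix(0, m, m, dimnames = list(model$lvars, model$lvars))
  Gm <- matrix(0, m, max(q, 0), dimnames = list(model$lvars, model$xvars))
  Ph <- matrix(0, max(q, 0), max(q, 0), dimnames = list(model$xvars, model$xvars))
  Th <- matrix(0, p, p, dimnames = list(model$yvars, model$yvars))
  Ps <- matrix(0, m, m, dimnames = list(model$lvars, model$lvars))
  pt <- model$partable
  vals <- pt$value
  vals[pt$free] <- theta[pt$free_id[pt$free]]
  for (r in seq_len(nrow(pt))) {
    v <- vals[r]; i <- pt$row[r]; j <- pt$col[r]
    switch(pt$mat[r],
           lambda = { L[i, j] <- v },
           beta   = { B[i, j] <- v },
           gamma  = { Gm[i, j] <- v },
           phi    = { Ph[i, j] <- v; Ph[j, i] <- v },
           theta  = { Th[i, j] <- v; Th[j, i] <- v },
           psi    = { Ps[i, j] <- v; Ps[j, i] <- v })
  }
  list(L = L, B = B, G = Gm, Ph = Ph, Th = Th, Ps = Ps)
}

#' Model-implied covariance matrix
#'
#' For measurement model `y = Lambda eta + eps` and structural model
#' `eta = B eta + Gamma x + zeta`, the implied covariance over `(y, x)` is
#' \deqn{\Sigma_{yy} = \Lambda A (\Gamma \Phi \Gamma' + \Psi) A' \Lambda' + \Theta,
#'   \quad \Sigma_{yx} = \Lambda A \Gamma \Phi, \quad \Sigma_{xx} = \Phi,}
#' with \eqn{A = (I - B)^{-1}}.
#'
#' @param model a [sem_model()].
#' @param theta free-parameter vector (raw scale) in parameter-table order.
#' @return Symmetric implied covariance matrix over the modeled variables
#'   (outcomes first, covariates after).
#' @export
implied_covariance <- function(model, theta) {
  mats <- model_matrices(model, theta)
  sem_sigma(mats)$Sigma
}

sem_sigma <- function(mats) {
  m <- ncol(mats$L); q <- ncol(mats$Ph)
  A <- if (m == 0L) matrix(0, 0, 0)
       else tryCatch(solve(diag(m) - mats$B), error = function(e)
         stopf("I - B is singular for the supplied parameters"))
  W <- mats$Ps
  if (q > 0) W <- W + mats$G %*% mats$Ph %*% t(mats$G)
  C_eta <- A %*% W %*% t(A)
  LA <- mats$L %*% A
  Syy <- mats$L %*% C_eta %*% t(mats$L) + mats$Th
  if (q > 0) {
    Syx <- LA %*% mats$G %*% mats$Ph
    Sigma <- rbind(cbind(Syy, Syx), cbind(t(Syx), mats$Ph))
  } else {
    Sigma <- Syy
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(c(rownames(mats$L), rownames(mats$Ph)),
                          c(rownames(mats$L), rownames(mats$Ph)))
  list(Sigma = Sigma, A = A, LA = LA, C_eta = C_eta, W = W)
}

#' Normal-theory maximum-likelihood discrepancy
#'
#' \deqn{F_{ML}(S, \Sigma) = \log|\Sigma| + tr(S \Sigma^{-1}) - \log|S| - p}
#' Non-negative, zero iff `S == Sigma`.
#'
#' @param S,Sigma positive-definite matrices of equal dimension.
#' @return Scalar discrepancy value.
#' @export
fml <- function(S, Sigma) {
  if (!isTRUE(all.equal(dim(S), dim(Sigma))))
    stopf("'S' and 'Sigma' must have equal dimension")
  p <- nrow(S)
  chS <- tryCatch(chol(S), error = function(e) stopf("'S' is not positive definite"))
  chSig <- tryCatch(chol(Sigma), error = function(e) stopf("'Sigma' is not positive definite"))
  ld_S <- 2 * sum(log(diag(chS)))
  ld_Sig <- 2 * sum(log(diag(chSig)))
  ld_Sig + sum(S * chol2inv(chSig)) - ld_S - p
}
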