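# Maximum-likelihood codon site models (M0, M1a, M2a, M3, M7, M8) over a
# fixed tree topology, likelihood-ratio tests between nested pairs, and
# Bayes empirical Bayes identification of positively selected sites.
#
# The substitution process is a 61-state codon model with
# transition/transversion ratio kappa, per-class omega, and empirical
# (F3x4) codon frequencies; site classes are a finite mixture. Branch
# lengths enter as a provided topology (typically the NJ tree) whose total
# length is rescaled by a free parameter optimized under M0 and reused by
# the richer models.

.postorderEdges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, elen = tr$edge.length, nnode = tr$Nnode,
    tip.label = tr$tip.label)
}

.tipStates <- function(aln, tip_label) {
  cm <- codonMatrix(aln)
  if (is.null(rownames(cm))) stop("alignment sequences must be named")
  if (!all(tip_label %in% rownames(cm)))
    stop("tree leaf set must equal alignment taxa")
  idx <- codonIndex(cm[tip_label, , drop = FALSE])
  matrix(as.integer(idx), nrow = length(tip_label))
}

# Coefficients of the unscaled mean substitution rate as a function of
# kappa and omega: rate = Stv + kappa*Sts + omega*(Ntv + kappa*Nts).
.rateCoefs <- function(pi) {
  type <- codonPairType()
  pp <- outer(pi, pi)
  c(Stv = sum(pp[type == 1]), Sts = sum(pp[type == 2]),
    Ntv = sum(pp[type == 3]), Nts = sum(pp[type == 4]))
}

.classRate <- function(coefs, kappa, omega) {
  coefs[["Stv"]] + kappa * coefs[["Sts"]] +
    omega * (coefs[["Ntv"]] + kappa * coefs[["Nts"]])
}

# Per-class site log-likelihoods under a common clock: branch lengths are
# expected substitutions per codon averaged over the class mixture (or per
# the supplied mean_rate), so high-omega classes evolve faster.
.classLogLik <- function(states, po, scale, pi, kappa, omegas,
                         props = NULL, mean_rate = NULL) {
  coefs <- .rateCoefs(pi)
  r <- vapply(omegas, function(w) .classRate(coefs, kappa, w), numeric(1))
  S <- if (!is.null(mean_rate)) mean_rate
    else if (!is.null(props)) sum(props * r)
    else mean(r)
  codon_class_loglik(states, po$edge, po$elen * scale, pi, kappa,
    as.numeric(omegas), r / S, codonPairType(), po$nnode)
}

.mixLogLik <- function(clw, props) {
  m <- apply(clw, 2, max)
  sum(log(colSums(props * exp(sweep(clw, 2, m)))) + m)
}

.model_npar <- c(M0 = 1L, M1a = 2L, M2a = 4L, M3 = 5L, M7 = 2L, M8 = 4L)

.beta_classes <- function(p, q, K = 10) {
  qbeta((2 * seq_len(K) - 1) / (2 * K), p, q)
}

# parameter vector <-> (omegas, props) per model; box bounds for L-BFGS-B
.model_spec <- function(model) {
  eps <- 1e-6
  switch(model,
    M0 = list(
      init = c(omega = 0.5),
      lower = c(1e-4), upper = c(99),
      classes = function(par) list(omega = par[1], prop = 1)
    ),
    M1a = list(
      init = c(p0 = 0.6, w0 = 0.2),
      lower = c(eps, eps), upper = c(1 - eps, 1),
      classes = function(par) list(omega = c(par[2], 1),
        prop = c(par[1], 1 - par[1]))
    ),
    M2a = list(
      init = c(p0 = 0.5, p1r = 0.6, w0 = 0.2, w2 = 3),
      lower = c(eps, eps, eps, 1), upper = c(1 - eps, 1 - eps, 1, 99),
      classes = function(par) {
        p0 <- par[1]
        p1 <- (1 - p0) * par[2]
        list(omega = c(par[3], 1, par[4]), prop = c(p0, p1, 1 - p0 - p1))
      }
    ),
    M3 = list(
      init = c(p0 = 0.4, p1r = 0.5, w0 = 0.1, w1 = 1, w2 = 5),
      lower = c(eps, eps, 1e-4, 1e-4, 1e-4),
      upper = c(1 - eps, 1 - eps, 99, 99, 99),
      classes = function(par) {
        p0 <- par[1]
        p1 <- (1 - p0) * par[2]
        list(omega = c(par[3], par[4], par[5]),
          prop = c(p0, p1, 1 - p0 - p1))
      }
    ),
    M7 = list(
      init = c(p = 0.5, q = 0.5),
      lower = c(0.005, 0.005), upper = c(99, 99),
      classes = function(par) list(omega = .beta_classes(par[1], par[2]),
        prop = rep(0.1, 10))
    ),
    M8 = list(
      init = c(p0 = 0.9, p = 0.5, q = 0.5, ws = 3),
      lower = c(eps, 0.005, 0.005, 1), upper = c(1 - eps, 99, 99, 99),
      classes = function(par) list(
        omega = c(.beta_classes(par[2], par[3]), par[4]),
        prop = c(rep(par[1] / 10, 10), 1 - par[1])
      )
    ),
    stop("unknown model code: ", model)
  )
}

#' Fit a codon site model by maximum likelihood
#'
#' @param aln a [CodonAlignment-class].
#' @param tree an `ape::phylo` with branch lengths; leaf set must equal the
#'   alignment taxa. Branch lengths are multiplied by a scale parameter
#'   (expected substitutions per codon): the scale is optimized when
#'   `optimize_scale` (default only under M0) and otherwise fixed at
#'   `scale`.
#' @param model one of "M0","M1a","M2a","M3","M7","M8".
#' @param kappa transition/transversion ratio; NULL (default) to estimate.
#' @param scale fixed tree scale when not optimized (use the M0 estimate).
#' @param optimize_scale logical; default TRUE for M0 only.
#' @param pi codon frequency vector (61); NULL = F3x4 from the alignment.
#' @param nstarts optimizer restarts from jittered initial points
#'   (default 3).
#' @param control list passed to [stats::optim()] (method L-BFGS-B).
#' @param seed seed for restart jitter.
#' @return A [SiteModelFit-class].
#' @export
fitSiteModel <- function(aln, tree, model = "M0", kappa = NULL, scale = 1,
                         optimize_scale = (model == "M0"), pi = NULL,
                         nstarts = 3, control = list(), seed = 1) {
  spec <- .model_spec(model)
  po <- .postorderEdges(tree)
  states <- .tipStates(aln, po$tip.label)
  if (is.null(pi)) pi <- codonFreqF3x4(codonMatrix(aln))
  est_kappa <- is.null(kappa)

  extra_init <- c(if (est_kappa) c(kappa = 2),
    if (optimize_scale) c(scale = 3))
  extra_lower <- c(if (est_kappa) 0.1, if (optimize_scale) 0.01)
  extra_upper <- c(if (est_kappa) 99, if (optimize_scale) 99)
  n_extra <- length(extra_init)
  nmod <- length(spec$init)

  obj <- function(par) {
    mp <- par[seq_len(nmod)]
    ex <- par[nmod + seq_len(n_extra)]
    kap <- if (est_kappa) ex[["kappa"]] else kappa
    sc <- if (optimize_scale) ex[[length(ex)]] else scale
    cls <- spec$classes(mp)
    clw <- .classLogLik(states, po, sc, pi, kap, cls$omega, props = cls$prop)
    ll <- .mixLogLik(clw, cls$prop)
    if (!is.finite(ll)) 1e10 else -ll
  }

  init <- c(spec$init, extra_init)
  lower <- c(spec$lower, extra_lower)
  upper <- c(spec$upper, extra_upper)
  ctrl <- modifyList(list(maxit = 300, factr = 1e9), control)

  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1, nstarts))) {
    p0 <- if (s == 1) init else {
      jit <- init * exp(runif(length(init), -0.7, 0.7))
      pmin(pmax(jit, lower + 1e-8), upper - 1e-8)
    }
    fit <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
        control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("optimizer non-convergence for model ", model)

  par <- best$par
  mp <- par[seq_len(nmod)]
  ex <- par[nmod + seq_len(n_extra)]
  kap <- if (est_kappa) ex[["kappa"]] else kappa
  sc <- if (optimize_scale) unname(ex[length(ex)]) else scale
  cls <- spec$classes(mp)
  clw <- .classLogLik(states, po, sc, pi, kap, cls$omega, props = cls$prop)

  coefs <- .rateCoefs(pi)
  rr <- vapply(cls$omega, function(w) .classRate(coefs, kap, w), numeric(1))
  params <- as.list(mp)
  params$kappa <- unname(kap)
  params$scale <- unname(sc)
  params$mean_rate <- sum(cls$prop * rr)
  params$pi <- pi
  new("SiteModelFit",
    model = model,
    logLik = -best$value,
    npar = .model_npar[[model]],
    params = params,
    siteClassLogLik = clw,
    classOmega = as.numeric(cls$omega),
    classProp = as.numeric(cls$prop),
    convergence = as.integer(best$convergence))
}

#' Likelihood-ratio test between nested site models
#'
#' Degrees of freedom equal the difference in free omega-structure
#' parameters (M0 vs M3: 4; M1a vs M2a: 2; M7 vs M8: 2); the p-value is the
#' upper chi-square tail.
#'
#' @param fit0,fit1 [SiteModelFit-class] objects, `fit0` nested in `fit1`.
#' @param tol tolerance on a negative likelihood difference before
#'   declaring an optimization failure (default 0.5).
#' @return list with `statistic` (2 Delta lnL, floored at 0), `df`, `p`.
#' @export
likelihoodRatioTest <- function(fit0, fit1, tol = 0.5) {
  nested <- list(c("M0", "M3"), c("M1a", "M2a"), c("M7", "M8"))
  ok <- any(vapply(nested, function(p)
    identical(p, c(fit0@model, fit1@model)), logical(1))) ||
    identical(fit0@model, fit1@model)
  if (!ok) stop("models are not a recognized nested pair")
  d <- fit1@logLik - fit0@logLik
  if (d < -tol)
    stop("optimization failure: alternative model has lower likelihood (",
      signif(d, 4), ")")
  stat <- max(2 * d, 0)
  df <- as.integer(fit1@npar - fit0@npar)
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else 1
  list(statistic = stat, df = df, p = p)
}

#' Bayes empirical Bayes site posteriors under M2a or M8
#'
#' Integrates the positive-selection class posterior per codon site over a
#' discrete parameter grid (uniform prior on the grid), holding kappa,
#' codon frequencies and branch lengths at their maximum-likelihood
#' estimates. For M2a the grid covers (p0, p1) on the simplex, omega0 in
#' (0,1) and omega2 in (1,11), each in 10 categories. For M8 the grid
#' covers p0 (10 categories), log-spaced beta shapes p, q in [0.05, 5] and
#' omega_s in (1,11); beta-class site likelihoods are interpolated from a
#' fixed omega grid on [0,1]. Positively selected sites (PSS) are those
#' with positive-class posterior above 0.95 (and a stricter 0.99 tier).
#'
#' @param fit a converged [SiteModelFit-class] for model M2a or M8.
#' @param aln the [CodonAlignment-class] used for the fit.
#' @param tree the tree used for the fit.
#' @return list of class `bebResult`: `sites` (data.frame with site,
#'   posterior probability of the positive class, posterior mean omega),
#'   `pss95`, `pss99` (integer site indices).
#' @export
bebSitePosteriors <- function(fit, aln, tree) {
  model <- fit@model
  if (!model %in% c("M2a", "M8"))
    stop("unsupported model for BEB: ", model)
  po <- .postorderEdges(tree)
  states <- .tipStates(aln, po$tip.label)
  pi <- fit@params$pi
  kap <- fit@params$kappa
  sc <- fit@params$scale
  nsite <- ncol(states)

  mr <- fit@params$mean_rate
  sitelik <- function(omegas) {
    # rows: omega values; cols: sites; log scale
    .classLogLik(states, po, sc, pi, kap, omegas, mean_rate = mr)
  }

  mid10 <- (2 * seq_len(10) - 1) / 20
  if (model == "M2a") {
    w0_grid <- mid10
    w2_grid <- 1 + 10 * mid10
    lw <- sitelik(c(w0_grid, 1, w2_grid))
    shift <- apply(lw, 2, max)
    f <- exp(sweep(lw, 2, shift))          # 21 x nsite, rescaled
    f0 <- f[1:10, , drop = FALSE]
    f1 <- f[11, ]
    f2 <- f[12:21, , drop = FALSE]
    pgrid <- expand.grid(p0 = mid10, p1 = mid10)
    pgrid <- pgrid[pgrid$p0 + pgrid$p1 <= 1, ]
    theta <- expand.grid(ip = seq_len(nrow(pgrid)), i0 = 1:10, i2 = 1:10)
    ntheta <- nrow(theta)
    logpost <- numeric(ntheta)
    Ppos <- matrix(0, ntheta, nsite)
    Mom <- matrix(0, ntheta, nsite)
    for (t in seq_len(ntheta)) {
      p0 <- pgrid$p0[theta$ip[t]]
      p1 <- pgrid$p1[theta$ip[t]]
      p2 <- 1 - p0 - p1
      fs <- p0 * f0[theta$i0[t], ] + p1 * f1 + p2 * f2[theta$i2[t], ]
      logpost[t] <- sum(log(fs))
      Ppos[t, ] <- p2 * f2[theta$i2[t], ] / fs
      Mom[t, ] <- (p0 * w0_grid[theta$i0[t]] * f0[theta$i0[t], ] +
        p1 * f1 + p2 * w2_grid[theta$i2[t]] * f2[theta$i2[t], ]) / fs
    }
  } else {
    wgrid01 <- seq(0, 1, by = 0.05)
    ws_grid <- 1 + 10 * mid10
    shapes <- exp(seq(log(0.05), log(5), length.out = 10))
    lw <- sitelik(c(wgrid01, ws_grid))
    shift <- apply(lw, 2, max)
    f <- exp(sweep(lw, 2, shift))
    f01 <- f[seq_along(wgrid01), , drop = FALSE]
    fws <- f[length(wgrid01) + seq_along(ws_grid), , drop = FALSE]
    interp <- function(w) {
      # linear interpolation of site likelihood in omega on [0,1]
      j <- pmin(pmax(findInterval(w, wgrid01), 1), length(wgrid01) - 1)
      a <- (w - wgrid01[j]) / (wgrid01[j + 1] - wgrid01[j])
      (1 - a) * f01[j, , drop = FALSE] + a * f01[j + 1, , drop = FALSE]
    }
    pq <- expand.grid(p = shapes, q = shapes)
    fbeta <- vector("list", nrow(pq))
    gbeta <- vector("list", nrow(pq))
    for (i in seq_len(nrow(pq))) {
      wk <- .beta_classes(pq$p[i], pq$q[i])
      fi <- interp(wk)
      fbeta[[i]] <- colMeans(fi)
      gbeta[[i]] <- colMeans(fi * wk)
    }
    theta <- expand.grid(ipq = seq_len(nrow(pq)), iw = seq_along(ws_grid),
      ip0 = seq_along(mid10))
    ntheta <- nrow(theta)
    logpost <- numeric(ntheta)
    Ppos <- matrix(0, ntheta, nsite)
    Mom <- matrix(0, ntheta, nsite)
    for (t in seq_len(ntheta)) {
      p0 <- mid10[theta$ip0[t]]
      fb <- fbeta[[theta$ipq[t]]]
      gb <- gbeta[[theta$ipq[t]]]
      fw <- fws[theta$iw[t], ]
      fs <- p0 * fb + (1 - p0) * fw
      logpost[t] <- sum(log(fs))
      Ppos[t, ] <- (1 - p0) * fw / fs
      Mom[t, ] <- (p0 * gb + (1 - p0) * ws_grid[theta$iw[t]] * fw) / fs
    }
  }
  logpost <- logpost - max(logpost)
  w <- exp(logpost)
  w <- w / sum(w)
  p_pos <- as.numeric(crossprod(w, Ppos))
  mean_om <- as.numeric(crossprod(w, Mom))
  sites <- data.frame(site = seq_len(nsite), p_positive = p_pos,
    mean_omega = mean_om)
  out <- list(sites = sites,
    pss95 = which(p_pos > 0.95),
    pss99 = which(p_pos > 0.99),
    model = model)
  class(out) <- "bebResult"
  out
}

#' @export
print.bebResult <- function(x, ...) {
  cat(sprintf("BEB (%s): %d sites with P>0.95 (%d with P>0.99) of %d\n",
    x$model, length(x$pss95), length(x$pss99), nrow(x$sites)))
  invisible(x)
}

#' Simulate a codon alignment along a tree
#'
#' Sites evolve independently under the 61-state codon model; each site is
#' assigned a class omega (either via `site_omega` directly or by sampling
#' `props` over `omegas`).
#'
#' @param tree `ape::phylo` with branch lengths in expected substitutions
#'   per codon.
#' @param ncodon number of codon sites.
#' @param omegas class omega values.
#' @param props class proportions (default: single class).
#' @param site_omega optional explicit per-site omega vector (overrides
#'   `omegas`/`props`).
#' @param kappa transition/transversion ratio (default 2).
#' @param pi codon frequencies (default uniform over sense codons).
#' @param seed integer seed.
#' @return list with `aln` (a [CodonAlignment-class]) and `site_omega`
#'   (the true per-site omega).
#' @export
simulateCodonAlignment <- function(tree, ncodon, omegas = 1, props = 1,
                                   site_omega = NULL, kappa = 2, pi = NULL,
                                   seed = 1) {
  set.seed(seed)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  if (is.null(site_omega)) {
    site_omega <- sample(omegas, ncodon, replace = TRUE, prob = props)
  }
  stopifnot(length(site_omega) == ncodon)
  po <- .postorderEdges(tree)
  ntip <- length(po$tip.label)
  nnode_total <- ntip + po$nnode
  root <- ntip + 1L
  type <- codonPairType()
  sense <- senseCodons()

  uom <- sort(unique(site_omega))
  # branch lengths are expected substitutions/codon for a neutral site;
  # other classes run proportionally faster or slower
  coefs <- .rateCoefs(pi)
  r1 <- .classRate(coefs, kappa, 1)
  mult <- setNames(vapply(uom, function(w)
    .classRate(coefs, kappa, w) / r1, numeric(1)), as.character(uom))
  states <- matrix(NA_integer_, nnode_total, ncodon)
  for (w in uom) {
    cols <- which(site_omega == w)
    states[root, cols] <- sample.int(61, length(cols), replace = TRUE,
      prob = pi)
  }
  # preorder traversal = reverse postorder
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]
    chi <- po$edge[e, 2]
    for (w in uom) {
      cols <- which(site_omega == w)
      P <- codon_pmat(type, pi, kappa, w,
        po$elen[e] * mult[[as.character(w)]])
      from <- states[par, cols]
      states[chi, cols] <- vapply(from, function(s)
        sample.int(61, 1, prob = pmax(P[s, ], 0)), integer(1))
    }
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(r)
    paste0(sense[r], collapse = ""))
  names(seqs) <- po$tip.label
  list(aln = codonAlignment(seqs), site_omega = site_omega)
}
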