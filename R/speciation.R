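# Equilibrium speciation of Fe3+ between two-site transferrin and an n:1
# chelator.
#
# Unknowns are the free ferric and free ligand concentrations; all other
# species follow from mass action:
#   tf1 = K1 [Fe] tf0,  tf2 = K2 [Fe] tf1,  FeL_i = beta_i [Fe] [L]^i.
# The two component balances (iron, ligand) are solved in log
# concentration variables, where both residuals are smooth and monotone
# in their own variable (the system is the gradient of a convex Gibbs-type
# potential), so a damped Newton iteration converges from a deterministic
# start and a nested bisection fallback is guaranteed.

# concentration floor keeping logarithms finite for zero pools (mol/L)
CONC_FLOOR <- 1e-30

#' Side-reaction coefficient for ligand protonation
#'
#' Fraction of free ligand present in the fully deprotonated, metal-reactive
#' form at a given pH:
#' \deqn{\alpha = \left(1 + \frac{[H^+]}{K_{a,n}} +
#'   \frac{[H^+]^2}{K_{a,n} K_{a,n-1}} + \dots\right)^{-1}}
#' with the acid dissociation constants taken from the most basic site down.
#'
#' @param pka Numeric vector of pKa values (ascending); `NULL` means no
#'   protonation correction (alpha = 1).
#' @param ph Working pH, in (0, 14).
#' @return Alpha in (0, 1].
#' @examples
#' side_reaction_coefficient(c(3.68, 9.77), 7.4)
#' @export
side_reaction_coefficient <- function(pka, ph) {
  check_number(ph, "ph", min = 0, max = 14, strict = TRUE)
  if (is.null(pka)) return(1)
  h <- 10^(-ph)
  inv <- 1
  term <- 1
  for (p in sort(pka, decreasing = TRUE)) {
    term <- term * h / 10^(-p)
    inv <- inv + term
  }
  1 / inv
}

#' Conditional stability constants at a working pH
#'
#' Corrects the cumulative stability constants of a chelator for ligand
#' protonation: \eqn{\log\beta_i' = \log\beta_i + i\,\log_{10}\alpha},
#' where alpha is the [side_reaction_coefficient()] at the given pH. If the
#' chelator carries no pKa values the constants are returned unchanged.
#'
#' @param chelator A [chelator()] object.
#' @param ph Working pH.
#' @param correct_protonation Set `FALSE` to return the raw constants even
#'   when pKa values are available.
#' @return Numeric vector of conditional log10 beta values, length `n_max`.
#' @examples
#' effective_betas(deferiprone(), 7.4)
#' effective_betas(deferiprone(), 7.4, correct_protonation = FALSE)
#' @export
effective_betas <- function(chelator, ph, correct_protonation = TRUE) {
  if (!inherits(chelator, "chelator"))
    abort_validation("'chelator' must be a chelator object")
  check_number(ph, "ph", min = 0, max = 14, strict = TRUE)
  if (!correct_protonation || is.null(chelator$pka)) return(chelator$log_beta)
  a <- side_reaction_coefficient(chelator$pka, ph)
  chelator$log_beta + seq_len(chelator$n_max) * log10(a)
}

# species concentrations and component totals implied by free (f, L)
.species_at <- function(f, L, k1, k2, tf_total, beta, ii) {
  r1 <- k1 * f
  r2 <- k1 * k2 * f * f
  d <- 1 + r1 + r2
  tf0 <- tf_total / d
  tf1 <- tf0 * r1
  tf2 <- tf0 * r2
  cx <- beta * f * L^ii
  list(f = f, L = L, tf0 = tf0, tf1 = tf1, tf2 = tf2, cx = cx,
       fe = f + tf1 + 2 * tf2 + sum(cx),
       lig = L + sum(ii * cx))
}

# 1-D solve (no chelator ligand): Brent bracket + Newton polish on ln[Fe]
.solve_fe_only <- function(fe_total, k1, k2, tf_total, rtol, max_iter) {
  g <- function(x) {
    s <- .species_at(exp(x), 0, k1, k2, tf_total, numeric(0), integer(0))
    (s$fe - fe_total) / fe_total
  }
  lo <- log(CONC_FLOOR) - 40
  hi <- log(fe_total) + 0.5
  x <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
  for (i in seq_len(50)) {
    gx <- g(x)
    if (abs(gx) <= rtol) break
    h <- 1e-7
    dg <- (g(x + h) - g(x - h)) / (2 * h)
    if (!is.finite(dg) || dg <= 0) break
    x <- x - gx / dg
  }
  if (abs(g(x)) > rtol)
    abort_solver("1-D iron balance did not reach rtol %.1e (residual %.3e)",
                 rtol, abs(g(x)))
  exp(x)
}

# nested bisection fallback for the 2-D system; guaranteed by monotonicity
.solve_nested_bisection <- function(fe_total, ligand_total, k1, k2, tf_total,
                                    beta, ii, n_bis = 120L) {
  solve_L <- function(f) {
    glig <- function(y) {
      s <- .species_at(f, exp(y), k1, k2, tf_total, beta, ii)
      (s$lig - ligand_total) / ligand_total
    }
    lo <- log(CONC_FLOOR) - 40
    hi <- log(ligand_total) + 1e-12
    if (glig(hi) < 0) return(exp(hi))
    for (i in seq_len(n_bis)) {
      mid <- (lo + hi) / 2
      if (glig(mid) > 0) hi <- mid else lo <- mid
    }
    exp((lo + hi) / 2)
  }
  gfe <- function(x) {
    f <- exp(x)
    s <- .species_at(f, solve_L(f), k1, k2, tf_total, beta, ii)
    (s$fe - fe_total) / fe_total
  }
  lo <- log(CONC_FLOOR) - 40
  hi <- log(fe_total) + 0.5
  for (i in seq_len(n_bis)) {
    mid <- (lo + hi) / 2
    if (gfe(mid) > 0) hi <- mid else lo <- mid
  }
  x <- (lo + hi) / 2
  f <- exp(x)
  c(f = f, L = solve_L(f))
}

# damped Newton on (ln[Fe], ln[L]) with numeric Jacobian
.solve_newton2 <- function(x0, y0, fe_total, ligand_total, k1, k2, tf_total,
                           beta, ii, rtol, max_iter) {
  g <- function(x, y) {
    s <- .species_at(exp(x), exp(y), k1, k2, tf_total, beta, ii)
    c((s$fe - fe_total) / fe_total, (s$lig - ligand_total) / ligand_total)
  }
  x <- x0; y <- y0
  gv <- g(x, y)
  for (it in seq_len(max_iter)) {
    if (max(abs(gv)) <= rtol) return(list(f = exp(x), L = exp(y), iter = it, ok = TRUE))
    h <- 1e-7
    gx <- g(x + h, y); gy <- g(x, y + h)
    J <- cbind((gx - gv) / h, (gy - gv) / h)
    step <- tryCatch(solve(J, -gv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(ok = FALSE, resid = gv))
    m <- max(abs(step))
    if (m > 5) step <- step * (5 / m)   # trust region: <= 5 log units
    t <- 1
    repeat {
      gn <- g(x + t * step[1], y + t * step[2])
      if (all(is.finite(gn)) && max(abs(gn)) < max(abs(gv))) break
      t <- t / 2
      if (t < 1e-12) return(list(ok = FALSE, resid = gv))
    }
    x <- x + t * step[1]; y <- y + t * step[2]
    gv <- gn
  }
  if (max(abs(gv)) <= rtol) list(f = exp(x), L = exp(y), iter = max_iter, ok = TRUE)
  else list(ok = FALSE, resid = gv)
}

#' Solve the ferric-iron speciation equilibrium
#'
#' Distributes total iron between free Fe3+, the three transferrin pools
#' (apo, lumped monoferric, diferric) and the chelator complexes FeL_1 ..
#' FeL_n at equilibrium, given total pools of transferrin protein, iron
#' and ligand. Transferrin binding uses the sequential conditional
#' constants K1, K2; chelator binding uses conditional cumulative
#' constants, by default protonation-corrected at the medium pH
#' (see [effective_betas()]).
#'
#' The solver works on (ln free Fe, ln free ligand). A damped Newton
#' iteration is started from a deterministic composition-only guess (the
#' one-dimensional iron balance at fully free ligand, then the ligand
#' balance at that iron level); if it does not reach `rtol` a nested
#' bisection on the two monotone balances is used, so the solve is
#' deterministic for fixed inputs and independent of any previous call.
#'
#' @param comp A [medium()] composition.
#' @param tf A [transferrin()] parameter set.
#' @param chelator A [chelator()] or `NULL`; if `NULL`, `ligand_total`
#'   must be 0.
#' @param correct_protonation Apply the ligand side-reaction correction
#'   (default `TRUE`).
#' @param rtol Relative tolerance on the component mass balances
#'   (default 1e-10).
#' @param max_iter Newton iteration cap.
#' @return An object of class `"speciation_state"`: free and bound species
#'   concentrations (mol/L), transferrin fractions `frac_apo`, `frac_mono`,
#'   `frac_holo`, site saturation, and the achieved balance residuals.
#' @examples
#' m <- medium(tf_total = 1.3e-6, fe_total = 2.6e-6)
#' solve_equilibrium(m)
#' @export
solve_equilibrium <- function(comp, tf = transferrin(), chelator = NULL,
                              correct_protonation = TRUE,
                              rtol = 1e-10, max_iter = 200L) {
  if (!inherits(comp, "medium")) abort_validation("'comp' must be a medium object")
  if (!inherits(tf, "transferrin")) abort_validation("'tf' must be a transferrin object")
  if (is.null(chelator) && comp$ligand_total > 0)
    abort_validation("ligand_total > 0 requires a chelator definition")
  lb <- if (!is.null(chelator)) {
    effective_betas(chelator, comp$ph, correct_protonation)
  } else numeric(0)
  beta <- 10^lb
  ii <- seq_along(beta)
  feT <- comp$fe_total; tfT <- comp$tf_total; lT <- comp$ligand_total
  k1 <- tf$k1; k2 <- tf$k2

  method <- "trivial"; iters <- 0L
  if (feT <= CONC_FLOOR) {
    f <- 0; L <- lT
  } else if (lT <= CONC_FLOOR) {
    f <- .solve_fe_only(feT, k1, k2, tfT, rtol, max_iter)
    L <- 0
    method <- "newton-1d"
  } else {
    # deterministic start: iron balance at L = ligand_total, then the
    # ligand balance at that iron level
    f0 <- tryCatch(
      .solve_fe_only_chel(feT, lT, k1, k2, tfT, beta, ii),
      error = function(e) feT * 1e-10
    )
    y0 <- .init_ligand(f0, lT, k1, k2, tfT, beta, ii)
    res <- .solve_newton2(log(f0), y0, feT, lT, k1, k2, tfT, beta, ii,
                          rtol, max_iter)
    if (isTRUE(res$ok)) {
      f <- res$f; L <- res$L; iters <- res$iter
      method <- "newton-2d"
    } else {
      fl <- .solve_nested_bisection(feT, lT, k1, k2, tfT, beta, ii)
      pol <- .solve_newton2(log(fl[["f"]]), log(fl[["L"]]), feT, lT,
                            k1, k2, tfT, beta, ii, rtol, 20L)
      if (isTRUE(pol$ok)) { f <- pol$f; L <- pol$L } else { f <- fl[["f"]]; L <- fl[["L"]] }
      method <- "bisection"
      s <- .species_at(f, L, k1, k2, tfT, beta, ii)
      r <- max(abs(s$fe - feT) / feT, abs(s$lig - lT) / lT)
      if (r > 100 * rtol)
        abort_solver("equilibrium solve failed: relative balance residual %.3e (Fe %.3g, Tf %.3g, L %.3g mol/L)",
                     r, feT, tfT, lT)
    }
  }

  s <- .species_at(f, L, k1, k2, tfT, beta, ii)
  cx <- s$cx
  names(cx) <- if (length(cx)) paste0("FeL", ii) else character(0)
  fr <- if (tfT > 0) {
    c(frac_apo = s$tf0 / tfT, frac_mono = s$tf1 / tfT, frac_holo = s$tf2 / tfT,
      tf_site_saturation = (s$tf1 + 2 * s$tf2) / (2 * tfT))
  } else c(frac_apo = NA_real_, frac_mono = NA_real_, frac_holo = NA_real_,
           tf_site_saturation = NA_real_)
  resid <- c(
    iron = abs(s$fe - feT) / max(feT, CONC_FLOOR),
    transferrin = abs(s$tf0 + s$tf1 + s$tf2 - tfT) / max(tfT, CONC_FLOOR),
    ligand = abs(s$lig - lT) / max(lT, CONC_FLOOR)
  )
  structure(
    list(free_fe = s$f, free_ligand = s$L,
         tf0 = s$tf0, tf1 = s$tf1, tf2 = s$tf2,
         complexes = cx,
         frac_apo = fr[["frac_apo"]], frac_mono = fr[["frac_mono"]],
         frac_holo = fr[["frac_holo"]],
         tf_site_saturation = fr[["tf_site_saturation"]],
         fe_total = feT, tf_total = tfT, ligand_total = lT,
         ph = comp$ph, bicarbonate = comp$bicarbonate,
         log_beta_conditional = lb,
         residuals = resid, rtol = rtol, method = method, iterations = iters,
         chelator_name = if (!is.null(chelator)) chelator$name else NA_character_),
    class = "speciation_state"
  )
}

# 1-D iron balance with ligand clamped at ligand_total (init heuristic)
.solve_fe_only_chel <- function(fe_total, L, k1, k2, tf_total, beta, ii) {
  g <- function(x) {
    s <- .species_at(exp(x), L, k1, k2, tf_total, beta, ii)
    (s$fe - fe_total) / fe_total
  }
  lo <- log(CONC_FLOOR) - 40
  hi <- log(fe_total) + 0.5
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root |> exp()
}

# ligand balance at fixed free iron (init heuristic), returns ln L
.init_ligand <- function(f, ligand_total, k1, k2, tf_total, beta, ii) {
  g <- function(y) {
    s <- .species_at(f, exp(y), k1, k2, tf_total, beta, ii)
    (s$lig - ligand_total) / ligand_total
  }
  hi <- log(ligand_total) + 1e-12
  if (g(hi) <= 0) return(hi)
  lo <- log(CONC_FLOOR) - 40
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("<speciation_state> pH %.2f  (solver: %s)\n", x$ph, x$method))
  cat(sprintf("  totals: Fe %.4g, Tf %.4g, ligand %.4g umol/L\n",
              x$fe_total * 1e6, x$tf_total * 1e6, x$ligand_total * 1e6))
  cat(sprintf("  free Fe3+ %.3e mol/L (pFe %.2f), free ligand %.4g umol/L\n",
              x$free_fe, if (x$free_fe > 0) -log10(x$free_fe) else NA,
              x$free_ligand * 1e6))
  if (x$tf_total > 0)
    cat(sprintf("  Tf: apo %.1f%%, mono %.1f%%, holo %.1f%% (site saturation %.1f%%)\n",
                100 * x$frac_apo, 100 * x$frac_mono, 100 * x$frac_holo,
                100 * x$tf_site_saturation))
  if (length(x$complexes))
    cat("  complexes (umol/L):",
        paste(sprintf("%s %.4g", names(x$complexes), x$complexes * 1e6),
              collapse = ", "), "\n")
  cat(sprintf("  max balance residual %.2e (rtol %.0e)\n",
              max(x$residuals), x$rtol))
  invisible(x)
}

#' Transferrin loading fractions of a solved state
#'
#' @param state A `"speciation_state"`.
#' @param tf_total Transferrin protein pool, mol/L; defaults to the pool
#'   stored in the state. Must be > 0 (fractions of an empty pool are
#'   undefined and raise an error rather than returning NaN).
#' @return Named numeric vector `frac_apo`, `frac_mono`, `frac_holo`,
#'   `tf_site_saturation`.
#' @export
tf_fractions <- function(state, tf_total = state$tf_total) {
  if (!inherits(state, "speciation_state"))
    abort_validation("'state' must be a speciation_state")
  if (!is.numeric(tf_total) || length(tf_total) != 1L || tf_total <= 0)
    abort_validation("transferrin fractions undefined: tf_total must be > 0")
  c(frac_apo = state$tf0 / tf_total,
    frac_mono = state$tf1 / tf_total,
    frac_holo = state$tf2 / tf_total,
    tf_site_saturation = (state$tf1 + 2 * state$tf2) / (2 * tf_total))
}

#' Compute pFe3+ of an iron binder
#'
#' pFe3+ is \eqn{-\log_{10}} of the free ferric concentration at the
#' conventional reference composition: 1 umol/L total iron, 10 umol/L
#' total ligand, pH 7.4. Higher pFe means stronger effective binding.
#' For transferrin the "10 umol/L total ligand" is interpreted as
#' 10 umol/L protein molecules (20 umol/L iron sites), the convention
#' under which literature transferrin pFe values are quoted.
#'
#' @param binder A [chelator()] or a [transferrin()] object.
#' @param fe_total Total iron, mol/L (default 1e-6).
#' @param ligand_total Total ligand, mol/L (default 1e-5).
#' @param ph Reference pH (default 7.4).
#' @param correct_protonation Apply the side-reaction correction for
#'   chelators with pKa values (default `TRUE`).
#' @return pFe3+ (dimensionless).
#' @examples
#' compute_pfe(deferiprone())
#' compute_pfe(deferiprone(), correct_protonation = FALSE)
#' compute_pfe(transferrin())
#' @export
compute_pfe <- function(binder, fe_total = 1e-6, ligand_total = 1e-5,
                        ph = 7.4, correct_protonation = TRUE) {
  if (inherits(binder, "chelator")) {
    comp <- medium(tf_total = 0, fe_total = fe_total,
                   ligand_total = ligand_total, ph = ph)
    st <- solve_equilibrium(comp, chelator = binder,
                            correct_protonation = correct_protonation)
  } else if (inherits(binder, "transferrin")) {
    comp <- medium(tf_total = ligand_total, fe_total = fe_total,
                   ligand_total = 0, ph = ph)
    st <- solve_equilibrium(comp, tf = binder)
  } else {
    abort_validation("'binder' must be a chelator or transferrin object")
  }
  -log10(st$free_fe)
}
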