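# Deterministic four-cell model of the hypertumour-cancer interface.
# Cells 1,2 are cancer cells (paying the CGF production cost c), cells 3,4
# hypertumour cells, with CGF concentrations g1 > g2 > g3 > g4 >= 0 falling
# away from the cancer interior. omega_i = F(g_i) - c [cancer] or F(g_i)
# [hypertumour], where F is a monotone CGF-to-fitness transformation.
# A CGF-reducing drug rescales each concentration to r*g_i (0 < r < 1);
# phi = d_omega(cancer) - d_omega(hypertumour) measures whether the drug
# promotes (phi < 0) or impedes (phi > 0) hypertumour progression.

#' CGF-to-fitness transformation functions
#'
#' * `LINEAR`: `F(t) = A t + B`, `A > 0`.
#' * `LOGISTIC`: `F(t) = k0 / (1 + exp(-k1 (t - 1))) + k2`, inflection at
#'   `t = 1`; by default `k0`, `k2` are solved from the boundary conditions
#'   `F(0) = 0`, `lim F = 1` via [solve_logistic_constants()].
#' * `CONVEX` / `CONCAVE`: normalised power families
#'   `F(t) = min(1, (t / scale)^p)` with `p > 1` (convex below the cap) or
#'   `0 < p < 1` (concave).
#' * `CUSTOM`: any monotonically increasing callable.
#'
#' @param family One of `"LINEAR"`, `"LOGISTIC"`, `"CONVEX"`, `"CONCAVE"`,
#'   `"CUSTOM"`.
#' @param A,B Linear slope (> 0) and intercept.
#' @param k0,k1,k2 Logistic constants; `k0`/`k2` default to the solved
#'   boundary values for the given steepness `k1`.
#' @param p Power exponent for `CONVEX` (> 1) / `CONCAVE` (in (0, 1)).
#' @param scale Concentration at which the power families reach 1.
#' @param fn Monotone function for `CUSTOM`.
#' @return An `acd_fitness_fn`.
#' @export
fitness_function <- function(family = c("LINEAR", "LOGISTIC", "CONVEX", "CONCAVE", "CUSTOM"),
                             A = 1, B = 0, k1 = 5, k0 = NULL, k2 = NULL,
                             p = NULL, scale = 5, fn = NULL) {
  family <- match.arg(family)
  pars <- switch(family,
    LINEAR = {
      if (A <= 0) stop("linear slope A must be positive", call. = FALSE)
      list(A = A, B = B)
    },
    LOGISTIC = {
      if (k1 <= 0) stop("logistic steepness k1 must be positive", call. = FALSE)
      if (is.null(k0) || is.null(k2)) {
        kk <- solve_logistic_constants(k1)
        if (is.null(k0)) k0 <- kk[["k0"]]
        if (is.null(k2)) k2 <- kk[["k2"]]
      }
      list(k0 = k0, k1 = k1, k2 = k2)
    },
    CONVEX = {
      if (is.null(p)) p <- 2
      if (p <= 1) stop("convex exponent must satisfy p > 1", call. = FALSE)
      list(p = p, scale = scale)
    },
    CONCAVE = {
      if (is.null(p)) p <- 0.5
      if (p <= 0 || p >= 1) stop("concave exponent must satisfy 0 < p < 1", call. = FALSE)
      list(p = p, scale = scale)
    },
    CUSTOM = {
      if (!is.function(fn)) stop("CUSTOM requires a callable fn", call. = FALSE)
      list(fn = fn)
    })
  structure(list(family = family, pars = pars), class = "acd_fitness_fn")
}

#' @export
print.acd_fitness_fn <- function(x, ...) {
  cat("<fitness function ", x$family, ": ",
      paste(names(x$pars), vapply(x$pars, function(v)
        if (is.function(v)) "<fn>" else format(v, digits = 6), ""),
        sep = "=", collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Solve the logistic boundary constants
#'
#' For `F(t) = k0 / (1 + exp(-k1 (t - 1))) + k2`, imposing `F(0) = 0` and
#' `lim F = 1` gives `k0 = 1 + exp(-k1)` and `k2 = -exp(-k1)`; in particular
#' `k0 + k2 = 1` exactly. For steepness 5 these round to 1.0067 and -0.0067.
#'
#' @param k1 Steepness (> 0).
#' @return Named numeric `c(k0 = , k2 = )`.
#' @export
solve_logistic_constants <- function(k1) {
  stopifnot(k1 > 0)
  c(k0 = 1 + exp(-k1), k2 = -exp(-k1))
}

#' Evaluate a CGF-to-fitness transformation
#'
#' @param f An `acd_fitness_fn`.
#' @param t Concentration(s), >= 0.
#' @return Fitness value(s).
#' @export
eval_F <- function(f, t) {
  if (any(t < 0)) stop("concentration t must be non-negative", call. = FALSE)
  p <- f$pars
  switch(f$family,
    LINEAR   = p$A * t + p$B,
    LOGISTIC = p$k0 / (1 + exp(-p$k1 * (t - 1))) + p$k2,
    CONVEX   = pmin(1, (t / p$scale)^p$p),
    CONCAVE  = pmin(1, (t / p$scale)^p$p),
    CUSTOM   = p$fn(t))
}

#' Interface scenario
#'
#' @param g Length-4 numeric of CGF concentrations at cells 1..4, strictly
#'   decreasing with `g[4] >= 0`.
#' @param c Production cost paid by the cancer cells (>= 0).
#' @param r Drug factor in (0, 1): concentrations are reduced to `r*g`.
#' @return An `acd_interface_scenario`.
#' @export
interface_scenario <- function(g, c = 0, r = 0.5) {
  g <- as.numeric(g)
  if (length(g) != 4L || any(diff(g) >= 0) || g[4] < 0)
    stop("need g1 > g2 > g3 > g4 >= 0", call. = FALSE)
  if (c < 0) stop("cost c must be non-negative", call. = FALSE)
  if (r <= 0 || r >= 1) stop("drug factor r must lie in (0, 1)", call. = FALSE)
  structure(list(g = g, c = c, r = r), class = "acd_interface_scenario")
}

#' Fitness of the four interface cells
#'
#' `omega1 = F(g1) - c`, `omega2 = F(g2) - c` (cancer pays the production
#' cost), `omega3 = F(g3)`, `omega4 = F(g4)` (hypertumours do not).
#'
#' @param s An `acd_interface_scenario`.
#' @param f An `acd_fitness_fn`.
#' @return Named numeric `omega1..omega4`.
#' @export
interface_fitness <- function(s, f) {
  Fg <- eval_F(f, s$g)
  stats::setNames(Fg - c(s$c, s$c, 0, 0), paste0("omega", 1:4))
}

#' Does the hypertumour stably proliferate?
#'
#' True iff `omega1 < omega3` and `omega2 < omega4`: each border cell, when
#' it dies, is more likely to be replaced from the hypertumour side.
#'
#' @param omega Length-4 numeric (as from [interface_fitness()]).
#' @return Logical.
#' @export
hypertumour_progresses <- function(omega) {
  omega[1] < omega[3] && omega[2] < omega[4]
}

#' Fitness changes induced by a CGF-reducing drug
#'
#' `d_omega_i = F(r g_i) - F(g_i)`; the production cost cancels.
#'
#' @param s An `acd_interface_scenario`.
#' @param f An `acd_fitness_fn`.
#' @return Named numeric `domega1..domega4`.
#' @export
drug_deltas <- function(s, f) {
  stats::setNames(eval_F(f, s$r * s$g) - eval_F(f, s$g), paste0("domega", 1:4))
}

#' Relative drug effect phi
#'
#' `phi = d_omega1 - d_omega3` (interior pair) or `d_omega2 - d_omega4`
#' (border pair). Negative phi means the drug promotes hypertumour
#' progression at the interface; positive phi means it impedes it.
#'
#' @param s An `acd_interface_scenario`.
#' @param f An `acd_fitness_fn`.
#' @param pair `"1-3"` or `"2-4"`.
#' @return Numeric phi.
#' @export
phi <- function(s, f, pair = c("1-3", "2-4")) {
  pair <- match.arg(pair)
  d <- drug_deltas(s, f)
  if (pair == "1-3") d[["domega1"]] - d[["domega3"]] else d[["domega2"]] - d[["domega4"]]
}

#' Sweep phi over a (concentration, ratio) grid
#'
#' For every cancer-side concentration `g` and hypertumour/cancer ratio
#' `rho` in (0, 1), computes `phi` for the pair `(g, rho * g)` at drug
#' factor `r`. The presets r = 0.8, 0.5, 0.2 correspond to drugs removing
#' 20%, 50% and 80% of the CGF.
#'
#' @param f An `acd_fitness_fn`.
#' @param g_values Cancer-side concentrations (default 101 points in
#'   \[0.05, 5\]).
#' @param ratio_values Ratios strictly in (0, 1) (default 99 points in
#'   \[0.01, 0.99\]).
#' @param r Drug factor in (0, 1).
#' @return An `acd_phi_grid` tibble with columns `g`, `ratio`, `phi`.
#' @export
phi_grid <- function(f, g_values = seq(0.05, 5, length.out = 101),
                     ratio_values = seq(0.01, 0.99, length.out = 99),
                     r = 0.5) {
  if (any(ratio_values >= 1) || any(ratio_values <= 0))
    stop("ratios must lie strictly in (0, 1)", call. = FALSE)
  if (r <= 0 || r >= 1) stop("drug factor r must lie in (0, 1)", call. = FALSE)
  grid <- tidyr::expand_grid(g = g_values, ratio = ratio_values)
  # phi(g, rho g) = [F(rg) - F(g)] - [F(r rho g) - F(rho g)], vectorised
  gh <- grid$g * grid$ratio
  val <- (eval_F(f, r * grid$g) - eval_F(f, grid$g)) -
         (eval_F(f, r * gh) - eval_F(f, gh))
  out <- tibble::tibble(g = grid$g, ratio = grid$ratio, phi = val)
  class(out) <- c("acd_phi_grid", class(out))
  attr(out, "drug_r") <- r
  attr(out, "family") <- f$family
  out
}

#' Randomised check of the linear-F theorem
#'
#' With linear `F(t) = A t + B` (`A > 0`) and any valid scenario,
#' `d_omega1 < d_omega3` and `d_omega2 < d_omega4` always hold
#' (algebraically `(r - 1) A g1 < (r - 1) A g3 <=> g1 > g3`): a
#' proportionate CGF-reducing drug always promotes hypertumour progression.
#' Samples random `(A, B, g, r)` and reports any counterexample.
#'
#' @param trials Number of random scenarios (>= 1).
#' @return List with `ok` (logical) and `counterexample` (`NULL`, or the
#'   first failing inputs).
#' @export
verify_linear_theorem <- function(trials = 10000L) {
  stopifnot(trials >= 1)
  for (i in seq_len(trials)) {
    A <- stats::runif(1, 0.01, 10)
    B <- stats::runif(1, -5, 5)
    g <- sort(stats::runif(4, 0.001, 10), decreasing = TRUE)
    if (any(diff(g) == 0)) next
    r <- stats::runif(1, 0.001, 0.999)
    f <- fitness_function("LINEAR", A = A, B = B)
    s <- interface_scenario(g, c = stats::runif(1, 0, 2), r = r)
    d <- drug_deltas(s, f)
    if (!(d[["domega1"]] < d[["domega3"]] && d[["domega2"]] < d[["domega4"]]))
      return(list(ok = FALSE, counterexample = list(A = A, B = B, g = g, r = r)))
  }
  list(ok = TRUE, counterexample = NULL)
}
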