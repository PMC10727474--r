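# Fitness of a cell given its genotype and the local factor concentrations.
# CGFs act positively and linearly through the matching receptor; secretion
# of CGFs and lactate costs fitness; lactate damages non-resistant cells;
# each mutated locus carries a small burden. A drug multiplies the received
# CGF concentration by r_k in (0, 1].

#' Simulator fitness parameters
#'
#' Defaults satisfy three qualitative orderings that the model requires
#' (checked by [check_fitness_regime()]): a full-hallmark cancer cell beats a
#' normal cell inside its own CGF cloud; a hypertumour beats a cancer cell at
#' an equal field (it skips the production costs); an isolated hypertumour
#' (no CGF) loses to a normal cell through its mutation burden.
#'
#' @param w_base Baseline fitness (> 0).
#' @param benefit_slope Linear benefit slope per CGF (length 3, >= 0).
#' @param production_cost Cost of secreting each CGF (length 3, >= 0).
#' @param lactate_cost Cost of secreting lactate (>= 0).
#' @param lactate_damage Damage per unit lactate to non-resistant cells (>= 0).
#' @param mutation_penalty Fitness burden per mutated locus (>= 0).
#' @param eps Non-negative fitness floor.
#' @return An `acd_fitness_params` list.
#' @export
fitness_params <- function(w_base = 1,
                           benefit_slope = c(1, 1, 1),
                           production_cost = c(0.3, 0.3, 0.3),
                           lactate_cost = 0.05,
                           lactate_damage = 0.5,
                           mutation_penalty = 0.05,
                           eps = 1e-6) {
  p <- list(w_base = w_base,
            benefit_slope = rep_len(benefit_slope, 3L),
            production_cost = rep_len(production_cost, 3L),
            lactate_cost = lactate_cost,
            lactate_damage = lactate_damage,
            mutation_penalty = mutation_penalty,
            eps = eps)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0) || p$w_base <= 0)
    stop("fitness parameters must be finite and non-negative, w_base > 0", call. = FALSE)
  structure(p, class = "acd_fitness_params")
}

#' Drug policy: multiplicative reduction of received CGF
#'
#' `r_k = 1` means no drug for factor k; the standard treatment halves the
#' effect of CGFs 1 and 2 (`drug_policy(on = TRUE)` gives r = (0.5, 0.5, 1)).
#'
#' @param r Length-3 numeric in (0, 1], per CGF.
#' @param on Convenience flag: `TRUE` is shorthand for `c(0.5, 0.5, 1)`.
#' @return An `acd_drug_policy` (numeric length 3).
#' @export
drug_policy <- function(r = NULL, on = FALSE) {
  if (is.null(r)) r <- if (isTRUE(on)) c(0.5, 0.5, 1) else c(1, 1, 1)
  r <- rep_len(as.numeric(r), 3L)
  if (any(r <= 0) || any(r > 1)) stop("drug multipliers must lie in (0, 1]", call. = FALSE)
  structure(r, class = "acd_drug_policy")
}

#' Fitness of a single cell
#'
#' `max(eps, w_base + sum_k rec_k * A_k * r_k * g_k - sum_k prod_k * c_k -
#' prod_lactate * c_L - (1 - lactate_resist) * d * g_lactate -
#' mu * n_mutated)`. Cells without the receptor for factor k gain nothing
#' from `g_k`; lactate-resistant cells take no lactate damage.
#'
#' @param g An `acd_genotype`.
#' @param local Named numeric of local concentrations
#'   (`GF1`, `GF2`, `GF3`, `LACTATE`), all >= 0.
#' @param params [fitness_params()].
#' @param drug [drug_policy()].
#' @return Non-negative fitness.
#' @export
cell_fitness <- function(g, local, params = fitness_params(), drug = drug_policy()) {
  g <- as_genotype(g)
  local <- local[factor_ids()]
  if (any(is.na(local)) || any(local < 0))
    stop("local concentrations must be non-negative for all four factors", call. = FALSE)
  rec <- unclass(g)[c("rec_gf1", "rec_gf2", "rec_gf3")]
  prod <- unclass(g)[c("prod_gf1", "prod_gf2", "prod_gf3")]
  w <- params$w_base +
    sum(rec * params$benefit_slope * unclass(drug) * local[1:3]) -
    sum(prod * params$production_cost) -
    g[["prod_lactate"]] * params$lactate_cost -
    (!g[["lactate_resist"]]) * params$lactate_damage * local[["LACTATE"]] -
    params$mutation_penalty * sum(unclass(g))
  max(params$eps, w)
}

#' Fitness map over a lattice
#'
#' Applies [cell_fitness()] at every live site using that site's own local
#' concentrations; vacant sites carry `NA`.
#'
#' @param lattice An `acd_lattice` (integer code matrix, `NA` = vacant).
#' @param fields An `acd_fieldset` of matching dimension.
#' @param params [fitness_params()].
#' @param drug [drug_policy()].
#' @return Numeric matrix of fitness values (`NA` at vacancies).
#' @export
fitness_map <- function(lattice, fields, params = fitness_params(), drug = drug_policy()) {
  if (!identical(dim(lattice), dim(fields[[1]])))
    stop("lattice and fields must share one dimension", call. = FALSE)
  codes <- lattice
  codes[is.na(codes)] <- 0L
  bit <- function(b) bitwAnd(codes, 2L^b) > 0L
  nmut <- matrix(popcount9(codes), nrow(lattice), ncol(lattice))
  w <- params$w_base +
    bit(4) * params$benefit_slope[1] * drug[1] * fields$GF1 +
    bit(5) * params$benefit_slope[2] * drug[2] * fields$GF2 +
    bit(6) * params$benefit_slope[3] * drug[3] * fields$GF3 -
    bit(0) * params$production_cost[1] -
    bit(1) * params$production_cost[2] -
    bit(2) * params$production_cost[3] -
    bit(3) * params$lactate_cost -
    (!bit(7)) * params$lactate_damage * fields$LACTATE -
    params$mutation_penalty * nmut
  w <- pmax(w, params$eps)   # matrix first: keeps dim
  w[is.na(lattice)] <- NA_real_
  w
}

# number of set bits among the 9 loci, vectorised over codes
popcount9 <- function(codes) {
  n <- 0L
  for (b in 0:8) n <- n + (bitwAnd(codes, 2L^b) > 0L)
  n
}

#' Check the qualitative fitness regime of a parameter set
#'
#' Asserts the three orderings the model's dynamics rely on, at the interior
#' field level implied by the kernel masses: (i) full cancer > normal inside
#' the cancer CGF cloud, (ii) hypertumour > cancer at an equal field,
#' (iii) normal > isolated hypertumour (both Warburg and non-Warburg).
#'
#' @param params [fitness_params()].
#' @param masses Named per-factor kernel masses (interior concentration of a
#'   large producer cluster equals the mass).
#' @return Invisibly `TRUE`; stops with a message if an ordering fails.
#' @export
check_fitness_regime <- function(params = fitness_params(),
                                 masses = kernel_config()$mass) {
  interior <- c(GF1 = masses[["GF1"]], GF2 = masses[["GF2"]],
                GF3 = masses[["GF3"]], LACTATE = masses[["LACTATE"]])
  zero <- c(GF1 = 0, GF2 = 0, GF3 = 0, LACTATE = 0)
  cancer <- make_archetype("CANCER_FULL")
  htw <- make_archetype("HT_WARBURG")
  htn <- make_archetype("HT_NO_WARBURG")
  normal <- make_archetype("NORMAL")
  if (cell_fitness(cancer, interior, params) <= cell_fitness(normal, interior, params))
    stop("regime check failed: cancer must beat normal inside its CGF cloud", call. = FALSE)
  if (cell_fitness(htw, interior, params) <= cell_fitness(cancer, interior, params))
    stop("regime check failed: hypertumour must beat cancer at equal field", call. = FALSE)
  if (cell_fitness(normal, zero, params) <= cell_fitness(htw, zero, params) ||
      cell_fitness(normal, zero, params) <= cell_fitness(htn, zero, params))
    stop("regime check failed: normal must beat an isolated hypertumour", call. = FALSE)
  invisible(TRUE)
}
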