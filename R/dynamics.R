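# One simulation time step: concentration fields -> fitness -> death
# (baseline + immune) -> fitness-proportional birth into vacancies ->
# one-way mutation -> metrics. The lattice is an integer matrix of genotype
# codes (0..511); NA marks a vacancy.
#
# Random-draw contract (shared bit-for-bit by the R phases here and the
# Rcpp core behind run_simulation()):
#   1. death:    one uniform per live site, column-major order;
#   2. birth:    one uniform per post-death vacancy with >= 1 live
#                von Neumann neighbour, column-major order; the parent is
#                picked by cumulative fitness weights over live neighbours
#                in the order up, down, left, right;
#   3. mutation: one uniform per unset locus (locus order 0..8) per live
#                site, column-major order.

#' Construct a uniform lattice
#'
#' @param width,height Grid dimensions (columns, rows).
#' @param fill An `acd_genotype` for every site, or `NA` for an empty grid.
#' @return An `acd_lattice`: integer matrix (`height` rows x `width` cols) of
#'   genotype codes with `NA` at vacancies.
#' @export
make_lattice <- function(width, height, fill = make_archetype("NORMAL")) {
  if (width < 1 || height < 1) stop("lattice dimensions must be positive", call. = FALSE)
  code <- if (length(fill) == 1L && is.na(fill)) NA_integer_ else genotype_to_code(fill)
  structure(matrix(code, nrow = height, ncol = width), class = "acd_lattice")
}

as_lattice <- function(m) {
  stopifnot(is.matrix(m))
  structure(matrix(as.integer(m), nrow(m), ncol(m)), class = "acd_lattice")
}

#' @export
print.acd_lattice <- function(x, ...) {
  live <- sum(!is.na(x))
  cat("<lattice ", ncol(x), " x ", nrow(x), ", ", live, " live cells>\n", sep = "")
  print(utils::head(class_counts(x)))
  invisible(x)
}

class_counts <- function(lattice) {
  codes <- lattice[!is.na(lattice)]
  cls <- class_table()[codes + 1L]
  tab <- tabulate(cls + 1L, nbins = 5L)
  stats::setNames(tab, cell_classes())
}

#' Per-step simulation configuration
#'
#' @param p_death Baseline per-cell death probability per step.
#' @param immune_alpha Immune detection probability scale
#'   (see [immune_detection_probability()]).
#' @param mutation_rate Per-locus per-step mutation probability.
#' @param model Diffusion model `"A"`, `"B"` or `"C"`.
#' @param fitness [fitness_params()].
#' @param drug [drug_policy()].
#' @param kernel_params [kernel_config()].
#' @return An `acd_step_config` list.
#' @export
step_config <- function(p_death = 0.05, immune_alpha = 0.05, mutation_rate = 1e-4,
                        model = "A", fitness = fitness_params(),
                        drug = drug_policy(), kernel_params = kernel_config()) {
  for (p in c(p_death = p_death, immune_alpha = immune_alpha, mutation_rate = mutation_rate))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  model <- match.arg(model, c("A", "B", "C"))
  structure(list(p_death = p_death, immune_alpha = immune_alpha,
                 mutation_rate = mutation_rate, model = model,
                 fitness = fitness, drug = drug, kernel_params = kernel_params),
            class = "acd_step_config")
}

#' Death phase
#'
#' Each live cell independently becomes vacant with probability
#' `1 - (1 - p_death) * (1 - p_imm)` where `p_imm` is its immune detection
#' probability. Vacant sites stay vacant.
#'
#' @param lattice An `acd_lattice`.
#' @param cfg An `acd_step_config`.
#' @return The post-death `acd_lattice`.
#' @export
death_phase <- function(lattice, cfg) {
  idx <- which(!is.na(lattice))          # column-major
  if (!length(idx)) return(lattice)
  u <- stats::runif(length(idx))
  codes <- lattice[idx]
  evade <- bitwAnd(codes, 2L^8L) > 0L
  p_imm <- ifelse(evade, 0, cfg$immune_alpha * popcount9(codes) / 9)
  p <- 1 - (1 - cfg$p_death) * (1 - p_imm)
  lattice[idx[u < p]] <- NA_integer_
  lattice
}

#' Birth phase
#'
#' Every vacancy with at least one live von Neumann neighbour is filled by an
#' exact genotype copy of one neighbour, chosen with probability proportional
#' to neighbour fitness. All fills use the pre-fill occupancy (synchronous:
#' offspring cannot parent within the same step). If every candidate fitness
#' is at or below the floor `eps`, the parent is chosen uniformly.
#'
#' @param lattice Post-death `acd_lattice`.
#' @param fitness Fitness matrix for the surviving cells (`NA` elsewhere),
#'   i.e. the pre-death fitness map with dead cells masked out.
#' @param eps Fitness floor used for the all-floor tie rule.
#' @return The post-birth `acd_lattice`.
#' @export
birth_phase <- function(lattice, fitness, eps = fitness_params()$eps) {
  nr <- nrow(lattice); nc <- ncol(lattice)
  old <- lattice
  vac <- which(is.na(old))               # column-major
  if (!length(vac)) return(lattice)
  # neighbour order: up, down, left, right
  for (v in vac) {
    r <- ((v - 1L) %% nr) + 1L
    cc <- ((v - 1L) %/% nr) + 1L
    nb <- integer(0)
    if (r > 1L) nb <- c(nb, v - 1L)
    if (r < nr) nb <- c(nb, v + 1L)
    if (cc > 1L) nb <- c(nb, v - nr)
    if (cc < nc) nb <- c(nb, v + nr)
    nb <- nb[!is.na(old[nb])]
    if (!length(nb)) next
    u <- stats::runif(1)
    w <- fitness[nb]
    if (all(w <= eps)) w <- rep(1, length(nb))
    tot <- sum(w)
    acc <- 0
    for (k in seq_along(nb)) {
      acc <- acc + w[k]
      if (u * tot < acc) { lattice[v] <- old[nb[k]]; break }
    }
  }
  lattice
}

#' Mutation phase
#'
#' One-way mutation applied to every live cell at the configured per-locus
#' rate, consuming one uniform per unset locus in the documented order.
#'
#' @param lattice An `acd_lattice`.
#' @param rate Per-locus mutation probability.
#' @return The mutated `acd_lattice`.
#' @export
mutation_phase <- function(lattice, rate) {
  if (rate == 0) return(lattice)
  idx <- which(!is.na(lattice))
  for (v in idx) {
    code <- lattice[v]
    for (b in 0:8) {
      if (bitwAnd(code, 2L^b) == 0L && stats::runif(1) < rate)
        code <- bitwOr(code, 2L^b)
    }
    lattice[v] <- code
  }
  lattice
}

#' Metrics of the current lattice state
#'
#' @param lattice An `acd_lattice`.
#' @param step Step index to record.
#' @return One-row tibble: `step`, `live_count`, the five class proportions
#'   among live cells, and `mutation_proportion` (mean mutated allele
#'   fraction over live cells).
#' @export
step_metrics <- function(lattice, step = NA_integer_) {
  codes <- lattice[!is.na(lattice)]
  n <- length(codes)
  props <- if (n) class_counts(lattice) / n else stats::setNames(rep(NA_real_, 5), cell_classes())
  tibble::tibble(
    step = as.integer(step),
    live_count = n,
    prop_normal = props[["NORMAL"]],
    prop_cancer = props[["CANCER"]],
    prop_hypertumour = props[["HYPERTUMOUR"]],
    prop_partial_ht = props[["PARTIAL_HYPERTUMOUR"]],
    prop_other = props[["OTHER_MUTANT"]],
    mutation_proportion = if (n) mean(popcount9(codes)) / 9 else NA_real_
  )
}

#' One full simulation step (reference R implementation)
#'
#' Phase order: producer masks and concentration fields from the current
#' occupancy; fitness map; death; birth (using survivors' fitness); mutation;
#' metrics. [run_simulation()] executes the identical loop in compiled code.
#'
#' @param lattice An `acd_lattice`.
#' @param cfg An `acd_step_config`.
#' @param kernels Kernel set for `cfg$model`, as from [kernel_set()].
#' @param step Step index recorded in the metrics row.
#' @return List with elements `lattice` and `metrics`.
#' @export
sim_step <- function(lattice, cfg, kernels = kernel_set(cfg$model, cfg$kernel_params),
                     step = NA_integer_) {
  fields <- compute_fields(producer_masks(lattice), kernels)
  fit <- fitness_map(lattice, fields, cfg$fitness, cfg$drug)
  lat <- death_phase(lattice, cfg)
  fit[is.na(lat)] <- NA_real_            # survivors keep their pre-death fitness
  lat <- birth_phase(lat, fit, cfg$fitness$eps)
  lat <- mutation_phase(lat, cfg$mutation_rate)
  list(lattice = lat, metrics = step_metrics(lat, step))
}

#' Run a simulation
#'
#' Deterministic given `(initial, cfg, n_steps, seed)`: replaying the same
#' seed reproduces the identical time series bit for bit. The loop runs in
#' compiled code (`use_cpp = TRUE`, the default) or through [sim_step()];
#' both consume R's random stream in the same documented order and produce
#' identical results for the same seed.
#'
#' @param initial An `acd_lattice`.
#' @param cfg An `acd_step_config`.
#' @param n_steps Number of steps (>= 1).
#' @param seed Integer seed.
#' @param use_cpp Use the compiled core (default) or the R reference loop.
#' @return An `acd_sim`: list with `metrics` (tibble, one row per step),
#'   `final_lattice`, `config`, `n_steps`, `seed`.
#' @export
run_simulation <- function(initial, cfg = step_config(), n_steps = 1000L,
                           seed = 1L, use_cpp = TRUE) {
  stopifnot(n_steps >= 1)
  kernels <- kernel_set(cfg$model, cfg$kernel_params)
  set.seed(as.integer(seed))
  if (use_cpp) {
    par <- c(cfg$fitness$benefit_slope, unclass(cfg$drug), cfg$fitness$production_cost,
             cfg$fitness$lactate_cost, cfg$fitness$lactate_damage,
             cfg$fitness$mutation_penalty, cfg$fitness$w_base, cfg$fitness$eps,
             cfg$p_death, cfg$immune_alpha, cfg$mutation_rate)
    res <- cpp_run(unclass(initial), lapply(kernels, `[[`, "weights"), par,
                   class_table(), as.integer(n_steps))
    metrics <- tibble::as_tibble(as.data.frame(res$metrics))
    names(metrics) <- c("step", "live_count", "prop_normal", "prop_cancer",
                        "prop_hypertumour", "prop_partial_ht", "prop_other",
                        "mutation_proportion")
    metrics$step <- as.integer(metrics$step)
    metrics$live_count <- as.integer(metrics$live_count)
    final <- as_lattice(res$lattice)
  } else {
    lat <- initial
    rows <- vector("list", n_steps)
    for (s in seq_len(n_steps)) {
      out <- sim_step(lat, cfg, kernels, step = s)
      lat <- out$lattice
      rows[[s]] <- out$metrics
    }
    metrics <- dplyr::bind_rows(rows)
    final <- lat
  }
  structure(list(metrics = metrics, final_lattice = final, config = cfg,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "acd_sim")
}

#' @export
print.acd_sim <- function(x, ...) {
  cat("<acd_sim: ", x$n_steps, " steps, seed ", x$seed, ">\n", sep = "")
  print(utils::tail(x$metrics, 3))
  invisible(x)
}
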