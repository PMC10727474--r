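# Experiment layer: the standard initial geometry (a rectangular-ring cancer
# cluster with an implanted centre), the scenario matrix (centre fill x drug
# x diffusion model), replicate ensembles and the 0.5-threshold conditional
# analysis of divergent final states.

#' Default initial geometry
#'
#' A 100 x 100 field of normal tissue; a centred 22 x 22 block of
#' full-hallmark cancer cells; inside it a centred 12-wide x 7-tall hole.
#' Because 22 - 7 is odd the hole cannot sit exactly centred vertically; the
#' extra row goes below centre. 0-based inclusive bounds: block rows/cols
#' 39..60, hole cols 44..55, hole rows 46..52.
#'
#' @param width,height Field size.
#' @param ring Side of the square cancer block.
#' @param hole_w,hole_h Width and height of the implanted centre.
#' @return A geometry list.
#' @export
geometry_config <- function(width = 100L, height = 100L, ring = 22L,
                            hole_w = 12L, hole_h = 7L) {
  g <- list(width = as.integer(width), height = as.integer(height),
            ring = as.integer(ring), hole_w = as.integer(hole_w),
            hole_h = as.integer(hole_h))
  if (g$ring > min(g$width, g$height))
    stop("cancer block does not fit in the field", call. = FALSE)
  if (g$hole_w > g$ring || g$hole_h > g$ring)
    stop("hole larger than the cancer block", call. = FALSE)
  g
}

#' Experiment scenario
#'
#' @param centre_fill What occupies the implanted centre: `"NORMAL_CONTROL"`
#'   (control), `"HT_WARBURG"` or `"HT_NO_WARBURG"`.
#' @param drug_on Apply the drug that halves the effect of CGFs 1 and 2.
#' @param model Diffusion model `"A"`, `"B"` or `"C"`.
#' @param n_steps Steps per replicate.
#' @param n_replicates Number of replicates.
#' @param base_seed Replicate `i` runs with seed `base_seed + i`.
#' @return An `acd_scenario` list.
#' @export
scenario <- function(centre_fill = "HT_NO_WARBURG", drug_on = FALSE, model = "A",
                     n_steps = 3000L, n_replicates = 20L, base_seed = 1L) {
  centre_fill <- match.arg(centre_fill, c("NORMAL_CONTROL", "HT_WARBURG", "HT_NO_WARBURG"))
  model <- match.arg(model, c("A", "B", "C"))
  if (n_steps < 1 || n_replicates < 1)
    stop("n_steps and n_replicates must be >= 1", call. = FALSE)
  structure(list(centre_fill = centre_fill, drug_on = isTRUE(drug_on), model = model,
                 n_steps = as.integer(n_steps), n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed)),
            class = "acd_scenario")
}

#' Build the initial lattice of a scenario
#'
#' @param scn An `acd_scenario`.
#' @param geometry See [geometry_config()].
#' @return An `acd_lattice`.
#' @export
make_initial <- function(scn, geometry = geometry_config()) {
  g <- geometry
  lat <- make_lattice(g$width, g$height, make_archetype("NORMAL"))
  r0 <- (g$height - g$ring) %/% 2L + 1L     # 1-based top row of the block
  c0 <- (g$width - g$ring) %/% 2L + 1L
  rows <- r0:(r0 + g$ring - 1L)
  cols <- c0:(c0 + g$ring - 1L)
  lat[rows, cols] <- genotype_to_code(make_archetype("CANCER_FULL"))
  hr0 <- r0 + (g$ring - g$hole_h) %/% 2L    # extra row below centre
  hc0 <- c0 + (g$ring - g$hole_w) %/% 2L
  hrows <- hr0:(hr0 + g$hole_h - 1L)
  hcols <- hc0:(hc0 + g$hole_w - 1L)
  fill <- switch(scn$centre_fill,
                 NORMAL_CONTROL = make_archetype("NORMAL"),
                 HT_WARBURG = make_archetype("HT_WARBURG"),
                 HT_NO_WARBURG = make_archetype("HT_NO_WARBURG"))
  lat[hrows, hcols] <- genotype_to_code(fill)
  lat
}

#' Run a replicate ensemble for a scenario
#'
#' Replicate `i` (1..n) runs with seed `base_seed + i`. Drug-on maps to
#' `drug_policy(on = TRUE)` (r = 0.5, 0.5, 1).
#'
#' @param scn An `acd_scenario`.
#' @param cfg An `acd_step_config`; its `model` and `drug` are overridden by
#'   the scenario.
#' @param geometry See [geometry_config()].
#' @return An `acd_ensemble`: list with `replicates` (tibble of every
#'   replicate's per-step metrics, keyed by `replicate`), `summary`
#'   (per-step mean and sd of each metric), `finals` (one row per replicate,
#'   final step, plus `final_ht` = final hypertumour + partial hypertumour
#'   proportion) and `scenario`.
#' @export
run_ensemble <- function(scn, cfg = step_config(), geometry = geometry_config()) {
  cfg$model <- scn$model
  cfg$drug <- drug_policy(on = scn$drug_on)
  init <- make_initial(scn, geometry)
  reps <- purrr::map(seq_len(scn$n_replicates), function(i) {
    sim <- run_simulation(init, cfg, n_steps = scn$n_steps, seed = scn$base_seed + i)
    dplyr::mutate(sim$metrics, replicate = i, .before = 1)
  })
  replicates <- dplyr::bind_rows(reps)
  new_ensemble(replicates, scn)
}

new_ensemble <- function(replicates, scn) {
  metric_cols <- setdiff(names(replicates), c("replicate", "step"))
  summary <- replicates |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   list(mean = mean, sd = stats::sd)),
                     .groups = "drop")
  finals <- replicates |>
    dplyr::group_by(.data$replicate) |>
    dplyr::slice_max(.data$step, n = 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(final_ht = .data$prop_hypertumour + .data$prop_partial_ht)
  structure(list(replicates = replicates, summary = summary, finals = finals,
                 scenario = scn),
            class = "acd_ensemble")
}

#' @export
print.acd_ensemble <- function(x, ...) {
  s <- x$scenario
  cat("<acd_ensemble: ", nrow(x$finals), " replicates, fill ", s$centre_fill,
      ", model ", s$model, ", drug ", if (s$drug_on) "on" else "off", ">\n", sep = "")
  print(utils::tail(x$summary[, 1:6], 3))
  invisible(x)
}

#' Split an ensemble by final (partial) hypertumour proportion
#'
#' Divergent final states are analysed separately: replicates whose final
#' hypertumour + partial hypertumour proportion is at or above the threshold
#' versus those below it. Each group is re-aggregated; an empty group is
#' returned as `NULL` and flagged.
#'
#' @param ens An `acd_ensemble`.
#' @param threshold In (0, 1); default 0.5.
#' @return List with `above`, `below` (each an `acd_ensemble` or `NULL`) and
#'   `empty` (character vector naming empty groups).
#' @export
split_by_final_proportion <- function(ens, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  above_ids <- ens$finals$replicate[ens$finals$final_ht >= threshold]
  below_ids <- setdiff(ens$finals$replicate, above_ids)
  take <- function(ids) {
    if (!length(ids)) return(NULL)
    new_ensemble(dplyr::filter(ens$replicates, .data$replicate %in% ids), ens$scenario)
  }
  out <- list(above = take(above_ids), below = take(below_ids))
  out$empty <- c("above", "below")[vapply(out[1:2], is.null, logical(1))]
  out
}

#' The six standard scenarios of one diffusion model
#'
#' Three centre fills crossed with drug on/off. Runs last 10 000 steps,
#' except 30 000 for Model B with the drug off, whose final composition is
#' highly divergent and needs longer to settle.
#'
#' @param model `"A"`, `"B"` or `"C"`.
#' @param n_replicates Replicates per scenario (500 in the full design).
#' @param base_seed Base seed.
#' @return List of six `acd_scenario`s.
#' @export
scenario_matrix <- function(model = "A", n_replicates = 500L, base_seed = 1L) {
  fills <- c("NORMAL_CONTROL", "HT_WARBURG", "HT_NO_WARBURG")
  out <- list()
  for (fill in fills) {
    for (drug in c(FALSE, TRUE)) {
      n_steps <- if (model == "B" && !drug) 30000L else 10000L
      out[[length(out) + 1L]] <- scenario(fill, drug_on = drug, model = model,
                                          n_steps = n_steps,
                                          n_replicates = n_replicates,
                                          base_seed = base_seed)
    }
  }
  out
}
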