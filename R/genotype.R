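# Nine one-way boolean oncogene loci. Locus order is fixed and is also the
# serialization order (9-character 0/1 strings) and the bit order of the
# integer codes used on the lattice (bit 0 = prod_gf1 ... bit 8 = immune_evade).

#' Oncogene locus names, in canonical order
#'
#' The nine modelled oncogene loci: production of the three diffusible cancer
#' growth factors (CGFs) and of acidifying lactate (the Warburg effect),
#' reception of the three CGFs, resistance to lactate, and immune evasion.
#' Each locus is a one-way boolean "mutated?" flag: mutation turns a locus on
#' and no reverse mutation exists.
#'
#' @return Character vector of length 9.
#' @export
locus_names <- function() {
  c("prod_gf1", "prod_gf2", "prod_gf3", "prod_lactate",
    "rec_gf1", "rec_gf2", "rec_gf3", "lactate_resist", "immune_evade")
}

N_LOCI <- 9L

#' Construct a genotype
#'
#' @param ... Named logical locus values (any subset of [locus_names()]);
#'   unnamed loci default to `FALSE` (wild-type).
#' @return An `acd_genotype`: a named logical vector of length 9.
#' @examples
#' genotype()                      # wild-type
#' genotype(rec_gf1 = TRUE, rec_gf2 = TRUE)
#' @export
genotype <- function(...) {
  vals <- list(...)
  g <- stats::setNames(rep(FALSE, N_LOCI), locus_names())
  if (length(vals)) {
    nm <- names(vals)
    if (is.null(nm) || any(nm == ""))
      stop("all locus values must be named", call. = FALSE)
    bad <- setdiff(nm, locus_names())
    if (length(bad))
      stop("unknown locus: ", paste(bad, collapse = ", "), call. = FALSE)
    g[nm] <- vapply(vals, function(x) isTRUE(as.logical(x)), logical(1))
  }
  structure(g, class = "acd_genotype")
}

as_genotype <- function(x) {
  if (inherits(x, "acd_genotype")) return(x)
  if (is.logical(x) && length(x) == N_LOCI)
    return(structure(stats::setNames(x, locus_names()), class = "acd_genotype"))
  stop("cannot interpret object as a genotype", call. = FALSE)
}

#' @export
print.acd_genotype <- function(x, ...) {
  cat("<genotype ", genotype_to_string(x), "> class: ", classify(x), "\n", sep = "")
  invisible(x)
}

# integer code (0..511) <-> genotype; the lattice stores codes
genotype_to_code <- function(g) {
  g <- as_genotype(g)
  as.integer(sum(2L^(0:8L) * as.integer(unclass(g))))
}

code_to_genotype <- function(code) {
  stopifnot(code >= 0L, code <= 511L)
  bits <- as.logical(bitwAnd(as.integer(code), 2L^(0:8L)))
  structure(stats::setNames(bits, locus_names()), class = "acd_genotype")
}

#' Serialize a genotype as a 9-character 0/1 string
#'
#' Characters follow [locus_names()] order.
#'
#' @param g An `acd_genotype`.
#' @return A string such as `"111111111"`.
#' @export
genotype_to_string <- function(g) {
  paste(as.integer(unclass(as_genotype(g))), collapse = "")
}

#' @rdname genotype_to_string
#' @param s A 9-character string of 0s and 1s.
#' @export
genotype_from_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nchar(s) == N_LOCI)
  bits <- strsplit(s, "")[[1]]
  if (!all(bits %in% c("0", "1")))
    stop("genotype string must contain only 0 and 1", call. = FALSE)
  structure(stats::setNames(bits == "1", locus_names()), class = "acd_genotype")
}

#' Classify a genotype into a cell class
#'
#' Classes follow the CGF-emission-based definitions: a hypertumour responds
#' to all three CGFs and resists lactate but produces no CGF; a partial
#' hypertumour produces no CGF and responds to one or two (not three) of them;
#' a cancer cell (full hallmarks) both produces and receives all three CGFs.
#' Warburg status (`prod_lactate`) and immune evasion never affect the class.
#'
#' @param g An `acd_genotype`.
#' @return One of `"NORMAL"`, `"CANCER"`, `"HYPERTUMOUR"`,
#'   `"PARTIAL_HYPERTUMOUR"`, `"OTHER_MUTANT"`.
#' @export
classify <- function(g) {
  g <- as_genotype(g)
  cell_classes()[class_table()[genotype_to_code(g) + 1L] + 1L]
}

#' Cell class labels
#'
#' @return Character vector of the five mutually exclusive cell classes, in
#'   the order used by integer class codes (0-based) throughout the package.
#' @export
cell_classes <- function() {
  c("NORMAL", "CANCER", "HYPERTUMOUR", "PARTIAL_HYPERTUMOUR", "OTHER_MUTANT")
}

# 512-entry lookup: code -> 0-based class index. Built once at load.
class_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codes <- 0:511
      bit <- function(i) bitwAnd(codes, 2L^i) > 0L
      prod_any <- bit(0) | bit(1) | bit(2)
      n_rec <- bit(4) + bit(5) + bit(6)
      cls <- rep(4L, 512L)                               # OTHER_MUTANT
      cls[codes == 0L] <- 0L                             # NORMAL
      cls[bit(0) & bit(1) & bit(2) & n_rec == 3L] <- 1L  # CANCER
      cls[!prod_any & n_rec == 3L & bit(7)] <- 2L        # HYPERTUMOUR
      cls[!prod_any & (n_rec == 1L | n_rec == 2L)] <- 3L # PARTIAL_HYPERTUMOUR
      cls[codes == 0L] <- 0L
      tab <<- cls
    }
    tab
  }
})

#' One-way mutation of a genotype
#'
#' Each wild-type (FALSE) locus independently mutates (turns TRUE) with the
#' given per-locus probability. Mutated loci never revert.
#'
#' @param g An `acd_genotype`.
#' @param per_locus_rate Probability in \[0, 1\].
#' @return The mutated `acd_genotype`.
#' @export
mutate_genotype <- function(g, per_locus_rate) {
  g <- as_genotype(g)
  if (!is.numeric(per_locus_rate) || per_locus_rate < 0 || per_locus_rate > 1)
    stop("per_locus_rate must lie in [0, 1]", call. = FALSE)
  off <- which(!unclass(g))
  if (length(off)) {
    flip <- stats::runif(length(off)) < per_locus_rate
    g[off[flip]] <- TRUE
  }
  g
}

#' Fraction of mutated oncogene loci
#'
#' @param g An `acd_genotype`.
#' @return Number of TRUE loci divided by 9.
#' @export
mutated_fraction <- function(g) {
  sum(unclass(as_genotype(g))) / N_LOCI
}

#' Probability of immune detection and elimination
#'
#' Highly mutated cells are more likely to be detected by immune cells; the
#' probability is `alpha * mutated_fraction(g)`, except that a mutation at the
#' immune-evasion locus makes the cell invisible (probability 0).
#'
#' @param g An `acd_genotype`.
#' @param alpha Probability scale in \[0, 1\].
#' @return A probability in \[0, 1\].
#' @export
immune_detection_probability <- function(g, alpha) {
  g <- as_genotype(g)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (g[["immune_evade"]]) return(0)
  alpha * mutated_fraction(g)
}

#' Archetypal genotypes
#'
#' `NORMAL` is wild-type; `CANCER_FULL` carries the full hallmarks of cancer
#' (all nine loci mutated); `HT_WARBURG` is a cancer cell re-engineered not to
#' produce CGFs (retaining lactate production, all receptors, lactate
#' resistance and immune evasion); `HT_NO_WARBURG` additionally does not
#' produce lactate.
#'
#' @param name One of `"NORMAL"`, `"CANCER_FULL"`, `"HT_WARBURG"`,
#'   `"HT_NO_WARBURG"`.
#' @return An `acd_genotype`.
#' @export
make_archetype <- function(name) {
  name <- match.arg(name, c("NORMAL", "CANCER_FULL", "HT_WARBURG", "HT_NO_WARBURG"))
  g <- genotype()
  if (name == "NORMAL") return(g)
  g[] <- TRUE
  if (name == "CANCER_FULL") return(g)
  g[c("prod_gf1", "prod_gf2", "prod_gf3")] <- FALSE
  if (name == "HT_NO_WARBURG") g[["prod_lactate"]] <- FALSE
  g
}
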