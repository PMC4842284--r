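#' Compile and validate a metabolic network model for label simulation
#'
#' The simulator propagates positional isotopomer distributions exactly
#' (vectors over the 2^n labelings of each compound's tracer-element
#' backbone, n <= 12). A model lists compounds with atom counts, reactions
#' with per-atom maps, per-compound mixing fractions over producing
#' reactions, and source compounds with fixed labeling (the tracer
#' definition). Cycles are allowed.
#'
#' A model description is a list (or YAML file) with entries:
#' \describe{
#'   \item{compounds}{named atom counts, e.g. `list(GLC = 6, PYR = 3)`.}
#'   \item{reactions}{list of `list(id, product, substrates)`, each
#'     substrate a `list(compound, atoms, to)`: substrate atom indices
#'     `atoms` map one-to-one onto product positions `to`. The union of
#'     `to` over substrates must be a bijection onto the product's atoms.
#'     A reaction is a transfer (one substrate, all atoms), a cleavage
#'     (one substrate, subset of atoms), or a condensation (several
#'     substrates); the `type` field is optional and checked when given.}
#'   \item{mixing}{per product compound, named flux fractions over its
#'     producing reaction ids, summing to 1. A compound with a single
#'     producing reaction may omit its entry (fraction 1).}
#'   \item{sources}{per source compound either
#'     `list(labeled_positions =, fraction =, purity =)` — a mixture of a
#'     defined labeling pattern (per-position incorporation `purity`,
#'     default 1) with unlabeled material — or `list(distribution =)`, a
#'     full 2^n state vector.}
#' }
#'
#' @param x model description list, or path to a YAML file with the same
#'   structure.
#' @return validated object of class `network_model`.
#' @export
compile_model <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  stopifnot(is.list(x), !is.null(x$compounds), !is.null(x$reactions))
  compounds <- unlist(x$compounds)
  storage.mode(compounds) <- "integer"
  if (any(compounds < 1L) || any(compounds > 12L)) {
    stop("compound atom counts must be in 1..12")
  }
  reactions <- x$reactions
  ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate reaction id")
  names(reactions) <- ids
  for (r in reactions) {
    if (!r$product %in% names(compounds)) {
      stop(sprintf("reaction %s: dangling product compound '%s'", r$id, r$product))
    }
    np <- compounds[[r$product]]
    to_all <- integer(0)
    for (s in r$substrates) {
      if (!s$compound %in% names(compounds)) {
        stop(sprintf("reaction %s: dangling substrate compound '%s'",
                     r$id, s$compound))
      }
      atoms <- as.integer(s$atoms); to <- as.integer(s$to)
      ns <- compounds[[s$compound]]
      if (length(atoms) != length(to) || anyDuplicated(atoms) ||
          any(atoms < 1L) || any(atoms > ns)) {
        stop(sprintf("reaction %s: invalid atom map for substrate %s",
                     r$id, s$compound))
      }
      to_all <- c(to_all, to)
    }
    if (!identical(sort(to_all), seq_len(np))) {
      stop(sprintf("reaction %s: atom map is not a bijection onto %s's %d atoms",
                   r$id, r$product, np))
    }
    n_sub <- length(r$substrates)
    inferred <- if (n_sub > 1L) "condensation" else
      if (length(r$substrates[[1L]]$atoms) ==
          compounds[[r$substrates[[1L]]$compound]]) "transfer" else "cleavage"
    if (!is.null(r$type) && !identical(r$type, inferred)) {
      stop(sprintf("reaction %s: declared type '%s' but structure implies '%s'",
                   r$id, r$type, inferred))
    }
  }
  sources <- x$sources
  if (is.null(sources)) sources <- list()
  producers <- split(ids, vapply(reactions, function(r) r$product, character(1)))
  for (cmp in names(compounds)) {
    if (!cmp %in% names(sources) && is.null(producers[[cmp]])) {
      stop(sprintf("dangling compound '%s': neither a source nor produced by any reaction",
                   cmp))
    }
  }
  mixing <- if (is.null(x$mixing)) list() else lapply(x$mixing, unlist)
  for (cmp in names(producers)) {
    if (cmp %in% names(sources)) next
    prods <- producers[[cmp]]
    fr <- mixing[[cmp]]
    if (is.null(fr)) {
      if (length(prods) > 1L) {
        stop(sprintf("compound '%s' has %d producing reactions but no mixing fractions",
                     cmp, length(prods)))
      }
      fr <- stats::setNames(1, prods)
    }
    if (!setequal(names(fr), prods)) {
      stop(sprintf("mixing for '%s' names reactions that do not produce it", cmp))
    }
    if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9) {
      stop(sprintf("mixing fractions for '%s' must lie in [0,1] and sum to 1 (sum = %g)",
                   cmp, sum(fr)))
    }
    mixing[[cmp]] <- fr
  }
  src_dists <- lapply(names(sources), function(cmp) {
    if (!cmp %in% names(compounds)) {
      stop(sprintf("source '%s' is not a declared compound", cmp))
    }
    source_distribution(sources[[cmp]], compounds[[cmp]])
  })
  names(src_dists) <- names(sources)
  structure(list(compounds = compounds, reactions = reactions,
                 mixing = mixing, sources = src_dists,
                 producers = producers),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d compounds, %d reactions, %d sources\n",
              length(x$compounds), length(x$reactions), length(x$sources)))
  invisible(x)
}

# Positional labeling distribution of a source compound: vector over the
# 2^n states, bit (j-1) of the state index set <=> atom j labeled.
source_distribution <- function(spec, n) {
  if (!is.null(spec$distribution)) {
    d <- as.numeric(spec$distribution)
    if (length(d) != 2^n) {
      stop(sprintf("source distribution must have length 2^%d", n))
    }
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      stop("source distribution must be nonnegative and sum to 1")
    }
    return(d)
  }
  pos <- as.integer(spec$labeled_positions %||% integer(0))
  frac <- spec$fraction %||% 1
  purity <- spec$purity %||% 1
  stopifnot(all(pos >= 1L), all(pos <= n), frac >= 0, frac <= 1)
  d <- numeric(2^n)
  d[1L] <- 1 - frac
  # labeled material: each designated position carries label with `purity`
  lab <- 1
  for (j in seq_len(n)) {
    pj <- if (j %in% pos) purity else 0
    lab <- c(lab * (1 - pj), lab * pj)  # appends bit j as the high bit
  }
  d <- d + frac * lab
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Marginalize a 2^n state distribution onto an ordered atom subset.
marginalize_atoms <- function(dist, atoms) {
  n <- as.integer(log2(length(dist)))
  k <- length(atoms)
  if (k == 0L) return(1)
  s <- 0:(length(dist) - 1L)
  packed <- integer(length(dist))
  for (i in seq_len(k)) {
    packed <- packed + bitwAnd(bitwShiftR(s, atoms[[i]] - 1L), 1L) *
      bitwShiftL(1L, i - 1L)
  }
  out <- numeric(2^k)
  agg <- rowsum(dist, packed)
  out[as.integer(rownames(agg)) + 1L] <- agg
  out
}

# Distribution a reaction induces on its product: substrate distributions
# are marginalized onto the mapped atoms and combined as independent
# (outer product), then the bits are routed to the product positions.
induced_distribution <- function(reaction, state, n_product) {
  s_all <- 0:(2^n_product - 1L)
  res <- rep(1, 2^n_product)
  for (sub in reaction$substrates) {
    atoms <- as.integer(sub$atoms); to <- as.integer(sub$to)
    marg <- marginalize_atoms(state[[sub$compound]], atoms)
    idx <- integer(2^n_product)
    for (i in seq_along(to)) {
      idx <- idx + bitwAnd(bitwShiftR(s_all, to[[i]] - 1L), 1L) *
        bitwShiftL(1L, i - 1L)
    }
    res <- res * marg[idx + 1L]
  }
  res
}

#' Simulate tracer propagation to isotopic steady state
#'
#' Fixed-point iteration of the update rule: each non-source compound's
#' positional isotopomer distribution is the flux-fraction-weighted mixture
#' over its producing reactions of the distribution each reaction induces
#' (condensation products as outer products of independent substrate
#' distributions). Iteration starts from the unlabeled state; for acyclic
#' models the fixed point is reached in at most the longest-path number of
#' sweeps.
#'
#' @param model a [compile_model()] result.
#' @param max_iter sweep cap.
#' @param tol convergence tolerance on the max-abs state change.
#' @return named list of state distributions (class `isotopomer_state`)
#'   with attributes `iterations` (sweeps that changed the state) and
#'   `residual`.
#' @export
simulate_labeling <- function(model, max_iter = 10000L, tol = 1e-10) {
  stopifnot(inherits(model, "network_model"))
  state <- lapply(model$compounds, function(n) c(1, numeric(2^n - 1L)))
  for (cmp in names(model$sources)) state[[cmp]] <- model$sources[[cmp]]
  targets <- setdiff(names(model$compounds), names(model$sources))
  targets <- intersect(targets, names(model$producers))
  iterations <- 0L
  delta <- Inf
  for (sweep in seq_len(max_iter)) {
    new_state <- state
    for (cmp in targets) {
      fr <- model$mixing[[cmp]]
      acc <- 0
      for (rid in names(fr)) {
        acc <- acc + fr[[rid]] *
          induced_distribution(model$reactions[[rid]], state,
                               model$compounds[[cmp]])
      }
      new_state[[cmp]] <- acc
    }
    delta <- max(vapply(targets, function(cmp)
      max(abs(new_state[[cmp]] - state[[cmp]])), numeric(1)), 0)
    state <- new_state
    if (delta < tol) break
    iterations <- iterations + 1L
  }
  if (delta >= tol) {
    stop(sprintf("labeling did not converge in %d sweeps (residual %.3g)",
                 max_iter, delta))
  }
  structure(state, class = "isotopomer_state",
            iterations = iterations, residual = delta)
}

#' Mass isotopomer distribution of a fragment of a simulated compound
#'
#' Marginalizes the compound's positional distribution onto the atom
#' subset retained in the fragment and aggregates states by label count.
#'
#' @param state an [simulate_labeling()] result.
#' @param compound compound name.
#' @param atoms integer positions retained by the fragment; defaults to the
#'   full backbone. An empty subset yields the trivial MID `1`.
#' @return MID vector of length `length(atoms) + 1`.
#' @export
fragment_mid <- function(state, compound, atoms = NULL) {
  stopifnot(inherits(state, "isotopomer_state"))
  dist <- state[[compound]]
  if (is.null(dist)) stop(sprintf("unknown compound '%s'", compound))
  n <- as.integer(log2(length(dist)))
  if (is.null(atoms)) atoms <- seq_len(n)
  atoms <- as.integer(atoms)
  if (length(atoms) == 0L) return(1)
  if (any(atoms < 1L) || any(atoms > n) || anyDuplicated(atoms)) {
    stop("invalid atom subset")
  }
  marg <- marginalize_atoms(dist, atoms)
  k <- length(atoms)
  counts <- vapply(0:(2^k - 1L), popcount, integer(1))
  mid <- numeric(k + 1L)
  for (c_ in 0:k) mid[c_ + 1L] <- sum(marg[counts == c_])
  mid
}

popcount <- function(x) {
  n <- 0L
  while (x > 0L) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}

#' Generate a synthetic labeling dataset with ground truth
#'
#' Runs the simulator for every condition (mixing-fraction overrides) and
#' tracer (source overrides), emits per-compound fragment MIDs with
#' Gaussian measurement noise on the abundance scale (clamped and
#' renormalized), and optionally folds the natural-abundance envelope of
#' each fragment's non-tracer atoms into raw spectral intensities. Fragment
#' m/z labels for simulated fragments are synthetic (100 + 10 x atom count
#' + subset offset) unless given explicitly.
#'
#' @param model a [compile_model()] result.
#' @param conditions named list: condition label -> mixing overrides
#'   (named list compound -> named fraction vector over reaction ids).
#'   An empty list means the base model.
#' @param tracers named list: tracer label -> source overrides (named list
#'   compound -> source spec as in [compile_model()]).
#' @param fragments named list compound -> list of fragment specs
#'   `list(mz =, atoms =, formula =)`; default: one full-backbone fragment
#'   per non-source compound.
#' @param noise_sd Gaussian noise SD on the abundance scale (default 0.01,
#'   a typical GC-MS MID reproducibility).
#' @param natural_abundance fold envelopes into raw intensities (needs
#'   fragment formulas).
#' @param replicates replicate count per condition x tracer (default 3).
#' @param seed RNG seed (restores the caller's RNG state afterwards).
#' @param r2_range range from which simulated R^2 values are drawn under
#'   noise (0.9999 when `noise_sd = 0`).
#' @param table isotope table for the envelopes.
#' @return list with `dataset` (a [labeling_dataset()]), `truth`
#'   (`data.table`: `condition`, `tracer`, `compound_id`, `fragment_mz`,
#'   list column `mid`), and `mixing` (the per-condition flux fractions).
#' @export
generate_dataset <- function(model, conditions = list(base = list()),
                             tracers = NULL, fragments = NULL,
                             noise_sd = 0.01, natural_abundance = FALSE,
                             replicates = 3L, seed = 1L,
                             r2_range = c(0.985, 0.9995),
                             table = default_isotope_table()) {
  stopifnot(inherits(model, "network_model"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (is.null(tracers)) tracers <- list(tracer1 = list())
  if (is.null(fragments)) {
    # GC-MS spectra typically offer several fragments per compound: emit the
    # full backbone plus (when possible) a sub-fragment lacking atom 1, so
    # QC rules needing two passing fragments are exercisable by default
    targets <- setdiff(names(model$compounds), names(model$sources))
    fragments <- lapply(targets, function(cmp) {
      n <- model$compounds[[cmp]]
      frs <- list(list(mz = 100L + 10L * n, atoms = seq_len(n), formula = NULL))
      if (n >= 2L) {
        frs <- c(frs, list(list(mz = 100L + 10L * n - 15L,
                                atoms = 2:n, formula = NULL)))
      }
      frs
    })
    names(fragments) <- targets
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  rows <- list(); truth <- list(); mixing_used <- list()
  ri_map <- stats::setNames(
    1000 + 100 * seq_along(names(fragments)), names(fragments))
  for (tr in names(tracers)) {
    for (cond in names(conditions)) {
      variant <- apply_overrides(model, conditions[[cond]], tracers[[tr]])
      mixing_used[[paste(cond, tr, sep = "|")]] <- variant$mixing
      st <- simulate_labeling(variant)
      for (cmp in names(fragments)) {
        for (fr in fragments[[cmp]]) {
          true_mid <- fragment_mid(st, cmp, fr$atoms)
          truth[[length(truth) + 1L]] <- data.table::data.table(
            condition = cond, tracer = tr, compound_id = cmp,
            fragment_mz = as.integer(fr$mz), mid = list(true_mid))
          for (rep_ in seq_len(replicates)) {
            noisy <- true_mid
            if (noise_sd > 0) {
              noisy <- normalize_mid(pmax(true_mid +
                stats::rnorm(length(true_mid), 0, noise_sd), 0))
            }
            r2 <- if (noise_sd > 0) stats::runif(1, r2_range[1], r2_range[2])
                  else 0.9999
            raw <- NULL
            formula_str <- NA_character_
            if (!is.null(fr$formula)) {
              formula_str <- if (is.character(fr$formula)) fr$formula else
                format_hill_formula(fr$formula$counts)
              if (natural_abundance) {
                ef <- if (is.character(fr$formula))
                  elemental_formula(fr$formula, tracer_atoms = length(fr$atoms))
                else fr$formula
                env <- non_tracer_envelope(ef, table)
                total <- stats::rlnorm(1, log(1e6), 0.25)
                raw <- convolve_mids(noisy, env) * total
              }
            }
            rows[[length(rows) + 1L]] <- data.table::data.table(
              condition = cond, tracer = tr, replicate = rep_,
              compound_id = cmp, compound_name = cmp,
              retention_index = ri_map[[cmp]], derivative = NA_character_,
              fragment_mz = as.integer(fr$mz), formula = formula_str,
              r2 = r2, mid = list(noisy), raw = list(raw),
              is_contaminant = FALSE)
          }
        }
      }
    }
  }
  ds <- labeling_dataset(data.table::rbindlist(rows),
                         conditions = names(conditions),
                         tracers = names(tracers))
  list(dataset = ds, truth = data.table::rbindlist(truth),
       mixing = mixing_used)
}

# Apply per-condition mixing overrides and per-tracer source overrides,
# revalidating the touched entries.
apply_overrides <- function(model, mixing_overrides = list(),
                            source_overrides = list()) {
  out <- model
  for (cmp in names(mixing_overrides %||% list())) {
    fr <- unlist(mixing_overrides[[cmp]])
    prods <- model$producers[[cmp]]
    if (is.null(prods) || !setequal(names(fr), prods)) {
      stop(sprintf("mixing override for '%s' does not match its producing reactions",
                   cmp))
    }
    if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
      stop(sprintf("mixing override for '%s' must sum to 1", cmp))
    }
    out$mixing[[cmp]] <- fr
  }
  for (cmp in names(source_overrides %||% list())) {
    if (!cmp %in% names(model$sources)) {
      stop(sprintf("source override for non-source compound '%s'", cmp))
    }
    out$sources[[cmp]] <- source_distribution(source_overrides[[cmp]],
                                              model$compounds[[cmp]])
  }
  out
}

#' Packaged example model: toy glycolysis/TCA network
#'
#' A small network with the qualitative features a two-tracer labeling
#' study probes: glucose is cleaved into two pyruvate halves, a PDH-like
#' node mixes pyruvate-derived acetyl units with an unlabeled acetyl pool
#' (fraction `pdh_fraction` from pyruvate), citrate is a condensation of
#' the acetyl and oxaloacetate moieties, and a glutamate/2-oxoglutarate
#' exchange cycle provides an entry for glutamine carbon. Two tracers are
#' predefined: `glc12` (glucose labeled at positions 1,2) and `glnU`
#' (uniformly labeled glutamine).
#'
#' @param pdh_fraction flux fraction of acetyl units coming from pyruvate
#'   (the remainder is unlabeled exchange); the mixing node swept across
#'   conditions in the worked examples.
#' @return list with `model` (a [compile_model()] result) and `tracers`
#'   (source override list for [generate_dataset()]).
#' @export
example_model <- function(pdh_fraction = 0.9) {
  stopifnot(pdh_fraction >= 0, pdh_fraction <= 1)
  spec <- list(
    compounds = list(GLC = 6L, GLN = 5L, PYR = 3L, ACA = 2L, ACX = 2L,
                     CO2 = 1L, OAX = 4L, OAA = 4L, CIT = 6L, AKG = 5L,
                     GLU = 5L),
    reactions = list(
      list(id = "glyc_upper", product = "PYR",
           substrates = list(list(compound = "GLC", atoms = 1:3, to = 3:1))),
      list(id = "glyc_lower", product = "PYR",
           substrates = list(list(compound = "GLC", atoms = 4:6, to = 1:3))),
      list(id = "pdh", product = "ACA",
           substrates = list(list(compound = "PYR", atoms = 2:3, to = 1:2))),
      list(id = "ac_exchange", product = "ACA",
           substrates = list(list(compound = "ACX", atoms = 1:2, to = 1:2))),
      list(id = "pc", product = "OAA",
           substrates = list(list(compound = "PYR", atoms = 1:3, to = 1:3),
                             list(compound = "CO2", atoms = 1L, to = 4L))),
      list(id = "oaa_exchange", product = "OAA",
           substrates = list(list(compound = "OAX", atoms = 1:4, to = 1:4))),
      list(id = "cs", product = "CIT",
           substrates = list(list(compound = "ACA", atoms = 1:2, to = 1:2),
                             list(compound = "OAA", atoms = 1:4, to = 3:6))),
      list(id = "idh", product = "AKG",
           substrates = list(list(compound = "CIT", atoms = 2:6, to = 1:5))),
      list(id = "akg_from_glu", product = "AKG",
           substrates = list(list(compound = "GLU", atoms = 1:5, to = 1:5))),
      list(id = "gdh", product = "GLU",
           substrates = list(list(compound = "AKG", atoms = 1:5, to = 1:5))),
      list(id = "gls", product = "GLU",
           substrates = list(list(compound = "GLN", atoms = 1:5, to = 1:5)))
    ),
    mixing = list(
      PYR = list(glyc_upper = 0.5, glyc_lower = 0.5),
      ACA = list(pdh = pdh_fraction, ac_exchange = 1 - pdh_fraction),
      OAA = list(pc = 0.6, oaa_exchange = 0.4),
      AKG = list(idh = 0.7, akg_from_glu = 0.3),
      GLU = list(gdh = 0.6, gls = 0.4)
    ),
    sources = list(
      GLC = list(labeled_positions = integer(0), fraction = 0),
      GLN = list(labeled_positions = integer(0), fraction = 0),
      ACX = list(labeled_positions = integer(0), fraction = 0),
      CO2 = list(labeled_positions = integer(0), fraction = 0),
      OAX = list(labeled_positions = integer(0), fraction = 0)
    )
  )
  tracers <- list(
    glc12 = list(GLC = list(labeled_positions = c(1L, 2L), fraction = 0.995)),
    glnU = list(GLN = list(labeled_positions = 1:5, fraction = 0.98))
  )
  list(model = compile_model(spec), tracers = tracers)
}

#' Mixing overrides sweeping the PDH-like node of [example_model()]
#'
#' @param fractions pyruvate-derived acetyl fractions, one condition each.
#' @return named condition list for [generate_dataset()].
#' @export
pdh_sweep_conditions <- function(fractions = c(0.9, 0.7, 0.5, 0.3, 0.1)) {
  conds <- lapply(fractions, function(f) {
    list(ACA = c(pdh = f, ac_exchange = 1 - f))
  })
  names(conds) <- sprintf("pdh%02.0f", 100 * fractions)
  conds
}
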