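# Seeded synthetic-data generators.
#
# The generators emulate the statistical structure of the real inputs -- a
# hierarchical domain classification (H-groups containing F-groups
# containing domains) with a heavy-tailed topology frequency distribution,
# a configurable fraction of domains lacking a pure parallel sheet, and a
# bias against frustrated topologies -- without emulating real identifier
# formats, sequences or coordinates.  Every generator is fully determined
# by its seed.

#' Specification for a synthetic classification table
#'
#' @param n_h_groups Number of homology groups.
#' @param f_groups_per_h Range (min, max) of families per homology group.
#' @param domains_per_f Range (min, max) of domains per family.
#' @param topology_universe List of occupant vectors the generator draws
#'   from; defaults to the clash-free 3--6 strand set.
#' @param skew Concentration of the heavy-tailed topology frequency
#'   distribution in (0, 1): stick-breaking with breaking fraction `skew`,
#'   so larger values concentrate more mass on few topologies.
#' @param unlabeled_fraction Probability that a domain has no pure parallel
#'   sheet (empty topology label).
#' @param frustration_bias Multiplicative down-weighting of topologies with
#'   N_FabP > 0 or N_j > 1 (0 = frustrated topologies never drawn, 1 = no
#'   bias).
#' @param within_f_coherence Probability that a labelled domain repeats its
#'   family's ancestral topology rather than redrawing.
#' @param seed Integer seed; output is fully determined by it.
#' @return List of class `synthetic_table_spec`.
#' @export
synthetic_table_spec <- function(n_h_groups = 40L,
                                 f_groups_per_h = c(1L, 8L),
                                 domains_per_f = c(1L, 25L),
                                 topology_universe = NULL,
                                 skew = 0.5,
                                 unlabeled_fraction = 0.3,
                                 frustration_bias = 0.15,
                                 within_f_coherence = 0.9,
                                 seed = 1L) {
  stopifnot(n_h_groups >= 1L, skew > 0, skew < 1,
            unlabeled_fraction >= 0, unlabeled_fraction <= 1,
            frustration_bias >= 0, frustration_bias <= 1,
            within_f_coherence >= 0, within_f_coherence <= 1)
  if (is.null(topology_universe)) {
    all_t <- enumerate_topologies(3L, 6L)
    topology_universe <- Filter(is_clash_free, all_t)
  }
  if (!length(topology_universe)) stop("empty topology universe", call. = FALSE)
  structure(list(n_h_groups = as.integer(n_h_groups),
                 f_groups_per_h = as.integer(f_groups_per_h),
                 domains_per_f = as.integer(domains_per_f),
                 topology_universe = topology_universe,
                 skew = skew, unlabeled_fraction = unlabeled_fraction,
                 frustration_bias = frustration_bias,
                 within_f_coherence = within_f_coherence,
                 seed = as.integer(seed)),
            class = "synthetic_table_spec")
}

# Evaluate an expression under a private RNG stream so generators neither
# disturb nor depend on the caller's RNG state.
with_private_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Heavy-tailed probabilities over the universe by stick breaking: topology
# ranks are shuffled, then rank r receives skew * (1-skew)^(r-1) (renormalised),
# optionally damped for frustrated topologies.
topology_weights <- function(spec) {
  uni <- spec$topology_universe
  k <- length(uni)
  w <- spec$skew * (1 - spec$skew)^(seq_len(k) - 1L)
  w <- w[sample.int(k)]
  frustrated <- vapply(uni, function(t)
    count_fabp(t) > 0L || count_jumps(t) > 1L, logical(1))
  w[frustrated] <- w[frustrated] * spec$frustration_bias
  w / sum(w)
}

#' Generate a synthetic ECOD-like classification table
#'
#' Each homology group draws an ancestral topology from a heavy-tailed
#' distribution over the universe; families inherit it, and labelled
#' domains repeat their family's topology with probability
#' `within_f_coherence` (otherwise redrawn), so labels are correlated
#' within families as common ancestry would make them.  A fraction of
#' domains is unlabeled.
#'
#' @param spec A [synthetic_table_spec()].
#' @return ECOD-like data frame (see [read_ecod_table()]).
#' @export
generate_ecod_like_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_table_spec"))
  with_private_rng(spec$seed, {
    w <- topology_weights(spec)
    keys <- vapply(spec$topology_universe, function(t)
      format_topology(canonicalize_topology(t), "ascii"), character(1))
    draw <- function(n) keys[sample.int(length(keys), n, replace = TRUE, prob = w)]
    rows <- list()
    d_id <- 0L
    for (h in seq_len(spec$n_h_groups)) {
      h_topology <- draw(1L)
      nf <- sample(seq(spec$f_groups_per_h[1L], spec$f_groups_per_h[2L]), 1L)
      for (f in seq_len(nf)) {
        f_topology <- if (stats::runif(1) < spec$within_f_coherence) h_topology
                      else draw(1L)
        nd <- sample(seq(spec$domains_per_f[1L], spec$domains_per_f[2L]), 1L)
        labelled <- stats::runif(nd) >= spec$unlabeled_fraction
        coherent <- stats::runif(nd) < spec$within_f_coherence
        tp <- ifelse(labelled, ifelse(coherent, f_topology, draw(nd)),
                     NA_character_)
        d_id <- d_id + seq_len(nd)
        rows[[length(rows) + 1L]] <- data.frame(
          domain_id = sprintf("D%06d", d_id),
          h_group = sprintf("H%04d", h),
          f_group = sprintf("F%04d.%03d", h, f),
          topology = tp, stringsAsFactors = FALSE)
        d_id <- d_id[length(d_id)]
      }
    }
    as_ecod_table(do.call(rbind, rows))
  })
}

#' Generate synthetic sheet records
#'
#' Produces records with planted topologies plus, in configurable
#' proportions, records violating each extraction criterion: an
#' antiparallel adjacent pairing (i), a barrel (ii), strands split over two
#' sheets (iii), or a loop of 100 or more residues (iv).
#'
#' @param n Number of records.
#' @param topology_universe List of occupant vectors to plant; defaults to
#'   the clash-free 3--6 strand set.
#' @param violation_fractions Named numeric, proportions of records
#'   violating criteria `i`, `ii`, `iii`, `iv` (the remainder is valid).
#' @param seed Integer seed.
#' @return List of [sheet_record()]s; each carries the planted topology (or
#'   the violated criterion) in attributes `planted` / `violation`.
#' @export
generate_sheet_records <- function(n, topology_universe = NULL,
                                   violation_fractions = c(i = 0, ii = 0,
                                                           iii = 0, iv = 0),
                                   seed = 1L) {
  if (is.null(topology_universe)) {
    all_t <- enumerate_topologies(3L, 6L)
    topology_universe <- Filter(is_clash_free, all_t)
  }
  vf <- c(i = 0, ii = 0, iii = 0, iv = 0)
  vf[names(violation_fractions)] <- violation_fractions
  if (sum(vf) > 1) stop("violation fractions exceed 1", call. = FALSE)
  with_private_rng(seed, {
    kinds <- sample(c(names(vf), "valid"), n, replace = TRUE,
                    prob = c(vf, 1 - sum(vf)))
    lapply(seq_len(n), function(k) {
      occ <- topology_universe[[sample.int(length(topology_universe), 1L)]]
      occ <- canonicalize_topology(occ)
      nstr <- length(occ)
      strands <- data.frame(index = seq_len(nstr),
                            position = order(occ),
                            orientation = "up",
                            stringsAsFactors = FALSE)
      loops <- sample(2:60, nstr - 1L, replace = TRUE)
      rec <- switch(kinds[k],
        valid = sheet_record(sprintf("S%05d", k), strands, loops = loops),
        i = {
          r <- sheet_record(sprintf("S%05d", k), strands, loops = loops)
          flip <- sample.int(nrow(r$pairings), 1L)
          r$pairings$relative[flip] <- "antiparallel"
          r
        },
        ii = sheet_record(sprintf("S%05d", k), strands, barrel = TRUE,
                          loops = loops),
        iii = sheet_record(sprintf("S%05d", k), strands, sheet_count = 2L,
                           loops = loops),
        iv = {
          loops[sample.int(length(loops), 1L)] <- sample(100:300, 1L)
          sheet_record(sprintf("S%05d", k), strands, loops = loops)
        })
      attr(rec, "planted") <- format_topology(occ)
      attr(rec, "violation") <- if (kinds[k] == "valid") NA_character_ else kinds[k]
      rec
    })
  })
}

#' Generate lattice fixtures
#'
#' Hand-constructed conformations with known annotation values (straight
#' chain, U-shape, compact Hamiltonian path, FLS-containing and
#' reverse-FLS-containing chains) plus seeded random HP sequences, for
#' regression tests of the lattice operations.
#'
#' @param length Chain length for the random sequences (<= 16).
#' @param n_sequences Number of random HP sequences.
#' @param seed Integer seed.
#' @return List with `conformations` (named list of coordinate matrices,
#'   each with an `expected` attribute giving `c(n_c, n_penalty, n_fls)`)
#'   and `sequences` (character vector of H/P strings).
#' @export
generate_lattice_fixtures <- function(length = 10L, n_sequences = 20L,
                                      seed = 1L) {
  stopifnot(length >= 4L, length <= 16L)
  straight <- cbind(0:(length - 1L), 0L)
  u_shape <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L))
  # boustrophedon Hamiltonian path on the 4x4 square
  snake <- do.call(rbind, lapply(0:3, function(y) {
    xs <- if (y %% 2L == 0L) 0:3 else 3:0
    cbind(xs, y)
  }))
  # 6-residue chain whose forward direction holds one interior FLS (so one
  # penalty) while its chain reversal holds none: the model's asymmetry in
  # miniature
  fls_chain <- points_from_turns("SSLL")
  rev_chain <- reverse_conformation(fls_chain)
  expected <- function(m) {
    structure(m, expected = c(n_c = nrow(contact_map(m)), count_motifs(m)))
  }
  confs <- list(straight = straight, u_shape = u_shape, snake = snake,
                fls_chain = fls_chain, reverse_fls_chain = rev_chain)
  confs <- lapply(confs, function(m)
    expected(canonicalize_conformation(m)))
  seqs <- with_private_rng(seed, {
    vapply(seq_len(n_sequences), function(i)
      paste(sample(c("H", "P"), length, replace = TRUE), collapse = ""),
      character(1))
  })
  list(conformations = confs, sequences = seqs)
}
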