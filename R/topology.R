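#' @useDynLib frustfree, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
#' @keywords internal
"_PACKAGE"

# A pure parallel beta-sheet topology is the left-to-right order of the
# sequentially numbered strands across the sheet.  It is represented here as
# the integer vector of occupants: occupants[i] is the strand sitting at
# sheet position i.  The inverse map p = order(occupants) gives the sheet
# position p[k] of strand k.  All strands point the same way ("up"), so a
# topology and its left-right mirror image are the same fold; the canonical
# representative is the lexicographically smaller of the occupant vector and
# its reversal, which realises the n!/2 counting.

ARROW_UP <- "↑"
ARROW_DOWN <- "↓"

validate_occupants <- function(occupants) {
  occupants <- as.integer(occupants)
  n <- length(occupants)
  if (n < 2L) stop("a sheet topology needs at least 2 strands", call. = FALSE)
  if (!setequal(occupants, seq_len(n)))
    stop("occupants must be a permutation of 1..n (got: ",
         paste(occupants, collapse = ","), ")", call. = FALSE)
  occupants
}

#' Parse a topology string
#'
#' Accepts the arrow dialect used in topology diagrams (e.g. `"2↑1↑3↑"`),
#' the bare digit dialect (`"213"`), and the dash-separated dialect
#' (`"2-1-3"`, required for sheets with 10 or more strands).  Only pure
#' parallel sheets are supported: a down arrow is rejected.
#'
#' @param text Topology string in any accepted dialect.
#' @return Integer vector of occupants (strand index at each sheet position,
#'   left to right), exactly as written; use [canonicalize_topology()] to
#'   reduce to the canonical flip representative.
#' @examples
#' parse_topology("2↑1↑3↑")
#' parse_topology("2-1-3")
#' @export
parse_topology <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("topology must be a single character string", call. = FALSE)
  if (grepl(ARROW_DOWN, text, fixed = TRUE))
    stop("down-oriented strands are not supported (pure parallel sheets only)",
         call. = FALSE)
  stripped <- gsub(ARROW_UP, "", text, fixed = TRUE)
  if (grepl("-", stripped, fixed = TRUE)) {
    parts <- strsplit(stripped, "-", fixed = TRUE)[[1L]]
  } else {
    parts <- strsplit(stripped, "", fixed = TRUE)[[1L]]
  }
  if (!length(parts) || any(!grepl("^[0-9]+$", parts)))
    stop("cannot parse topology string: ", text, call. = FALSE)
  validate_occupants(as.integer(parts))
}

#' Format a topology as a string
#'
#' @param topology Integer vector of occupants.
#' @param dialect `"arrow"` (default) for `"2↑1↑3↑"`, `"ascii"` for `"2-1-3"`.
#' @return Character string.
#' @export
format_topology <- function(topology, dialect = c("arrow", "ascii")) {
  dialect <- match.arg(dialect)
  topology <- validate_occupants(topology)
  if (dialect == "arrow")
    paste0(paste0(topology, ARROW_UP), collapse = "")
  else
    paste(topology, collapse = "-")
}

#' Canonical flip representative of a topology
#'
#' A sheet read left-to-right and the same sheet read right-to-left are the
#' same fold; the canonical representative is the lexicographically smaller
#' of the two occupant vectors.
#'
#' @param topology Integer vector of occupants.
#' @return Integer vector, canonical occupants.
#' @export
canonicalize_topology <- function(topology) {
  topology <- validate_occupants(topology)
  flipped <- rev(topology)
  for (i in seq_along(topology)) {
    if (topology[i] < flipped[i]) return(topology)
    if (flipped[i] < topology[i]) return(flipped)
  }
  topology
}

#' Enumerate all canonical pure parallel sheet topologies
#'
#' There are n!/2 distinct topologies of n strands once a topology is
#' identified with its left-right flip.  For the default 3--6 strand range
#' the total is 435.
#'
#' @param n_min,n_max Strand count range (inclusive).
#' @param max_strands Resource guard: enumeration is factorial in n and is
#'   refused above this threshold.
#' @return List of canonical occupant vectors, in lexicographic order within
#'   each strand count, smaller sheets first.
#' @export
enumerate_topologies <- function(n_min = 3L, n_max = 6L, max_strands = 9L) {
  if (n_min < 2L || n_max < n_min)
    stop("need 2 <= n_min <= n_max", call. = FALSE)
  if (n_max > max_strands)
    stop("refusing exhaustive enumeration above ", max_strands,
         " strands (", factorial(n_max) / 2, " topologies); raise ",
         "`max_strands` explicitly if this is intended", call. = FALSE)
  out <- list()
  for (n in seq(n_min, n_max)) {
    perms <- all_permutations(n)
    keys <- vapply(perms, function(p) {
      paste(canonicalize_topology(p), collapse = "-")
    }, character(1))
    canon <- perms[!duplicated(keys)]
    canon <- lapply(canon, canonicalize_topology)
    ord <- order(vapply(canon, function(p) paste(sprintf("%02d", p), collapse = ""),
                        character(1)))
    out <- c(out, canon[ord])
  }
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}

#' Crossover connection geometry of a topology
#'
#' Every consecutive strand pair (k, k+1) in a pure parallel sheet is joined
#' by a crossover connection that leaves the top of strand k and enters the
#' bottom of strand k+1, passing over one face of the sheet.  Under the
#' right-handedness of crossover connections, the face is fixed by the
#' crossing direction: rightward connections (positive position change) run
#' over the front face, leftward over the back.  A global face flip leaves
#' every derived quantity unchanged.
#'
#' @param topology Integer vector of occupants.
#' @return Data frame with one row per connection k = 1..n-1: `delta`
#'   (signed sheet-position change p(k+1) - p(k)), `face` (`"front"` or
#'   `"back"`), `span_lo`, `span_hi` (the two positions, ordered), and
#'   `long_distance` (`TRUE` when the connection skips more than two
#'   intervening strands, i.e. |delta| >= 4).
#' @export
connection_geometry <- function(topology) {
  topology <- validate_occupants(topology)
  p <- order(topology)
  n <- length(p)
  delta <- p[-1L] - p[-n]
  data.frame(
    connection = seq_len(n - 1L),
    delta = delta,
    face = ifelse(delta > 0L, "front", "back"),
    span_lo = pmin(p[-n], p[-1L]),
    span_hi = pmax(p[-n], p[-1L]),
    long_distance = abs(delta) >= 4L
  )
}

#' Test a topology for clashing crossover connections
#'
#' Each connection is a monotone curve on its face from the top of the sheet
#' at position p(k) down to the bottom at position p(k+1).  Two connections
#' on the same face clash when the curves must cross: their order along the
#' top edge differs from their order along the bottom edge.  Connections on
#' opposite faces, nested connections and connections sharing a strand never
#' clash.
#'
#' @param topology Integer vector of occupants.
#' @return `TRUE` if no pair of connections clashes.
#' @export
is_clash_free <- function(topology) {
  topology <- validate_occupants(topology)
  p <- order(topology)
  n <- length(p)
  if (n < 4L) return(TRUE)  # fewer than 2 same-face crossing candidates never clash for n = 3 either, but cheap exit
  g <- connection_geometry(topology)
  for (a in seq_len(n - 2L)) {
    for (b in seq(a + 1L, n - 1L)) {
      if (g$face[a] != g$face[b]) next
      top <- sign(p[a] - p[b])
      bot <- sign(p[a + 1L] - p[b + 1L])
      if (top != 0L && bot != 0L && top != bot) return(FALSE)
    }
  }
  TRUE
}

#' Count jumps in a topology
#'
#' A jump is a pair of strands adjacent in sequence but not neighbouring in
#' the sheet.  Topologies with more than one jump are strongly disfavoured
#' in the structure database because long jumps raise the folding free
#' energy barrier.
#'
#' @param topology Integer vector of occupants.
#' @return Integer count N_j in 0..n-1.
#' @export
count_jumps <- function(topology) {
  topology <- validate_occupants(topology)
  p <- order(topology)
  sum(abs(diff(p)) > 1L)
}

#' Count frustrated alpha-beta-unit pairings
#'
#' Connection k carries an alpha-helix on its face, forming the alpha-beta
#' unit (helix k, strand k+1).  Two such units whose strands sit at adjacent
#' sheet positions (a hydrogen-bonded parallel pair) while their helices lie
#' on opposite faces cannot simultaneously satisfy the right-handedness,
#' alpha-beta orientation and register-shift rules: the pairing is
#' frustrated.
#'
#' @param topology Integer vector of occupants.
#' @return Integer count N_FabP.
#' @export
count_fabp <- function(topology) {
  topology <- validate_occupants(topology)
  p <- order(topology)
  n <- length(p)
  if (n < 3L) return(0L)
  g <- connection_geometry(topology)
  cnt <- 0L
  for (k in seq_len(n - 2L)) {
    for (m in seq(k + 1L, n - 1L)) {
      if (abs(p[k + 1L] - p[m + 1L]) == 1L && g$face[k] != g$face[m])
        cnt <- cnt + 1L
    }
  }
  cnt
}

#' Chain-reversed topology
#'
#' Reversing the N- to C-terminal direction relabels strand k as strand
#' n+1-k while keeping every strand at its sheet position.  The result is
#' reduced to its canonical flip representative, so applying the operation
#' twice is the identity on canonical forms.
#'
#' @param topology Integer vector of occupants.
#' @return Integer vector, canonical occupants of the reversed topology.
#' @export
reverse_topology <- function(topology) {
  topology <- validate_occupants(topology)
  p <- order(topology)
  canonicalize_topology(order(rev(p)))
}

#' Topology-level relative contact order
#'
#' The mean sequence separation of hydrogen-bonded strand pairs, normalised
#' by the number of strands: with the n-1 sheet-adjacent position pairs of
#' an open sheet, betaRCO = (1 / (n (n-1))) * sum |strand index difference|.
#' Sequential ladders score the minimum 1/n; the value is bounded by
#' (n-1)/n.  Superfolds empirically occupy an intermediate band.
#'
#' @param topology Integer vector of occupants.
#' @return Numeric value in \[1/n, (n-1)/n\].
#' @export
beta_rco <- function(topology) {
  topology <- validate_occupants(topology)
  n <- length(topology)
  sum(abs(diff(topology))) / (n * (n - 1L))
}

#' Classify one topology
#'
#' Assembles the full per-topology record: jump count, frustrated-pairing
#' count, clash flag, betaRCO, terminal edge flags, long-distance crossover
#' flag and the reversed topology.  A topology is frustration-free when
#' N_FabP = 0 and N_j <= 1.
#'
#' @param topology Integer vector of occupants (canonicalized internally).
#' @return One-row data frame with columns `topology`, `n_strands`,
#'   `clash_free`, `n_jumps`, `n_fabp`, `beta_rco`, `n_term_edge`,
#'   `c_term_edge`, `reverse_topology`, `long_distance`,
#'   `frustration_free`.
#' @export
classify_topology <- function(topology) {
  topology <- canonicalize_topology(topology)
  p <- order(topology)
  n <- length(p)
  g <- connection_geometry(topology)
  nj <- count_jumps(topology)
  nf <- count_fabp(topology)
  data.frame(
    topology = format_topology(topology, "ascii"),
    n_strands = n,
    clash_free = is_clash_free(topology),
    n_jumps = nj,
    n_fabp = nf,
    beta_rco = beta_rco(topology),
    n_term_edge = p[1L] %in% c(1L, n),
    c_term_edge = p[n] %in% c(1L, n),
    reverse_topology = format_topology(reverse_topology(topology), "ascii"),
    long_distance = any(g$long_distance),
    frustration_free = nf == 0L && nj <= 1L,
    stringsAsFactors = FALSE
  )
}

#' Classify a set of topologies
#'
#' @param topologies List of occupant vectors, as returned by
#'   [enumerate_topologies()].
#' @return Data frame, one row per topology (see [classify_topology()]).
#' @export
classify_topologies <- function(topologies) {
  do.call(rbind, lapply(topologies, classify_topology))
}

round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarise a topology set
#'
#' Computes the frustration grid, terminal edge-position statistics, the
#' count of reverse-asymmetric frustrated pairs and the frustration-free
#' member list for a (filtered) topology set.
#'
#' @param topologies List of occupant vectors or a classification data frame
#'   from [classify_topologies()].
#' @param clash_free_only Restrict to clash-free topologies (default `TRUE`).
#' @param max_fabp,max_jumps Optional upper bounds applied as additional
#'   filters.
#' @param pair_universe Universe over which reverse-asymmetric pairs
#'   (exactly one member of \{T, reverse(T)\} with N_FabP = 0) are counted:
#'   the filtered set (default) or all input topologies.
#' @return List with elements `n_topologies`, `grid` (3 x 6 matrix, rows
#'   N_FabP 0/1/2+, columns N_j 0..5), `edge_percent` (named numeric,
#'   one-decimal half-up rounding), `edge_count`, `pair_count`,
#'   `frustration_free` (character vector of ASCII topology labels) and
#'   `classification` (the filtered data frame).
#' @export
summarize_topology_set <- function(topologies, clash_free_only = TRUE,
                                   max_fabp = NULL, max_jumps = NULL,
                                   pair_universe = c("filtered", "all")) {
  pair_universe <- match.arg(pair_universe)
  cls <- if (is.data.frame(topologies)) topologies else classify_topologies(topologies)
  keep <- rep(TRUE, nrow(cls))
  if (clash_free_only) keep <- keep & cls$clash_free
  if (!is.null(max_fabp)) keep <- keep & cls$n_fabp <= max_fabp
  if (!is.null(max_jumps)) keep <- keep & cls$n_jumps <= max_jumps
  sub <- cls[keep, , drop = FALSE]

  grid <- matrix(0L, nrow = 3L, ncol = 6L,
                 dimnames = list(n_fabp = c("0", "1", "2+"),
                                 n_jumps = as.character(0:5)))
  if (nrow(sub)) {
    fr <- pmin(sub$n_fabp, 2L) + 1L
    jc <- pmin(sub$n_jumps, 5L) + 1L
    for (i in seq_len(nrow(sub))) grid[fr[i], jc[i]] <- grid[fr[i], jc[i]] + 1L
  }

  edge_count <- c(n_term = sum(sub$n_term_edge), c_term = sum(sub$c_term_edge))
  edge_percent <- if (nrow(sub)) round_half_up(100 * edge_count / nrow(sub))
                  else c(n_term = 0, c_term = 0)

  pairs_from <- if (pair_universe == "filtered") sub else cls
  pair_count <- count_reverse_asymmetric_pairs(pairs_from)

  list(
    n_topologies = nrow(sub),
    grid = grid,
    edge_percent = edge_percent,
    edge_count = edge_count,
    pair_count = pair_count,
    frustration_free = sub$topology[sub$frustration_free],
    classification = sub
  )
}

# Unordered {T, reverse(T)} pairs, T != reverse(T), with exactly one member
# free of frustrated pairings.  Both members must belong to the set.
count_reverse_asymmetric_pairs <- function(cls) {
  fabp <- setNames(cls$n_fabp, cls$topology)
  seen <- character(0)
  cnt <- 0L
  for (i in seq_len(nrow(cls))) {
    t <- cls$topology[i]
    r <- cls$reverse_topology[i]
    if (t == r || t %in% seen || !(r %in% names(fabp))) next
    seen <- c(seen, t, r)
    if ((fabp[[t]] == 0L) != (fabp[[r]] == 0L)) cnt <- cnt + 1L
  }
  cnt
}

#' Write a topology classification table to TSV
#'
#' @param classification Data frame from [classify_topologies()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_topology_table <- function(classification, path) {
  cols <- c("topology", "n_strands", "clash_free", "n_jumps", "n_fabp",
            "beta_rco", "n_term_edge", "c_term_edge", "reverse_topology",
            "long_distance")
  utils::write.table(classification[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
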