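# Occurrence Frequency of Homologous-group in a Topology (OFHT).
#
# The statistic is computed over a hierarchical domain classification table:
# homology (H) groups contain family (F) groups contain domains.  For a
# topology T and H-group i,
#
#   OR(T, i)  = (1 / N_family(i)) * sum_j N_domain(T, i, j) / N_domain(i, j)
#   OFHT(T)   = sum_i OR(T, i)
#
# so OFHT(T) is the number of independent homology groups adopting T,
# weighted within each group by how consistently its families do so.
# Domains without a pure parallel sheet carry no topology label; they count
# in every denominator but no numerator.

#' Read / write an ECOD-like classification table
#'
#' The table is a TSV with header `domain_id  h_group  f_group  topology`;
#' an empty topology field marks a domain without a pure parallel sheet.
#' Topology labels in either dialect are canonicalized on ingest so that
#' flip-equivalent labels aggregate.
#'
#' @param path File path.
#' @param table Data frame with the four columns above.
#' @return `read_ecod_table`: the validated data frame;
#'   `write_ecod_table`: the path, invisibly.
#' @export
read_ecod_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = "", fileEncoding = "UTF-8")
  as_ecod_table(df)
}

#' @rdname read_ecod_table
#' @export
write_ecod_table <- function(table, path) {
  table <- as_ecod_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

as_ecod_table <- function(df) {
  need <- c("domain_id", "h_group", "f_group", "topology")
  if (!all(need %in% names(df)))
    stop("table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  df <- df[, need]
  if (anyDuplicated(df$domain_id))
    stop("duplicated domain_id in table", call. = FALSE)
  fh <- unique(df[, c("h_group", "f_group")])
  if (anyDuplicated(fh$f_group))
    stop("each f_group must belong to exactly one h_group", call. = FALSE)
  lab <- !is.na(df$topology) & nzchar(df$topology)
  df$topology[lab] <- vapply(df$topology[lab], function(s)
    format_topology(canonicalize_topology(parse_topology(s)), "ascii"),
    character(1))
  df$topology[!lab] <- NA_character_
  df
}

#' Occupation ratio of a topology in one homology group
#'
#' The mean, over the group's families, of the fraction of each family's
#' domains with the given topology.
#'
#' @param table ECOD-like table (see [read_ecod_table()]).
#' @param topology Topology in any accepted string dialect or as an occupant
#'   vector.
#' @param h_group Homology group identifier.
#' @return Numeric value in \[0, 1\].
#' @export
compute_or <- function(table, topology, h_group) {
  table <- as_ecod_table(table)
  key <- topology_key(topology)
  sub <- table[table$h_group == h_group, , drop = FALSE]
  if (!nrow(sub)) stop("h_group not found: ", h_group, call. = FALSE)
  fracs <- tapply(sub$topology, sub$f_group,
                  function(tp) mean(!is.na(tp) & tp == key))
  mean(fracs)
}

topology_key <- function(topology) {
  if (is.character(topology)) topology <- parse_topology(topology)
  format_topology(canonicalize_topology(topology), "ascii")
}

#' Compute OFHT for every topology in a table
#'
#' @param table ECOD-like table.
#' @return Data frame (class `ofht_table`) with columns `topology`, `ofht`,
#'   sorted by decreasing OFHT; attribute `n_h_groups` records the number of
#'   homology groups, the upper bound for the total OFHT mass.
#' @export
compute_ofht <- function(table) {
  table <- as_ecod_table(table)
  h_groups <- unique(table$h_group)
  acc <- new.env(parent = emptyenv())
  for (h in h_groups) {
    sub <- table[table$h_group == h, , drop = FALSE]
    fams <- split(sub$topology, sub$f_group)
    nfam <- length(fams)
    for (fam in fams) {
      lab <- fam[!is.na(fam)]
      if (!length(lab)) next
      fr <- table(lab) / length(fam)
      for (tp in names(fr)) {
        prev <- if (is.null(acc[[tp]])) 0 else acc[[tp]]
        acc[[tp]] <- prev + fr[[tp]] / nfam
      }
    }
  }
  tps <- ls(acc)
  out <- data.frame(topology = tps,
                    ofht = vapply(tps, function(t) acc[[t]], numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ofht, out$topology), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_h_groups") <- length(h_groups)
  class(out) <- c("ofht_table", class(out))
  out
}

#' Categorize topologies by OFHT
#'
#' Superfolds are topologies adopted by three or more homology groups
#' (OFHT >= 3); normal folds have 0 < OFHT < 3; the rest of the universe is
#' unobserved.
#'
#' @param ofht `ofht_table` from [compute_ofht()].
#' @param universe List of occupant vectors (or ASCII labels) defining the
#'   theoretically possible topologies, typically the clash-free set.
#' @return List with `table` (topology, ofht, category over the universe),
#'   `counts` (named: superfold / normal / unobserved) and
#'   `outside_universe` (observed topologies not in the universe, e.g.
#'   non-clash-free observations, kept in a separate bucket).
#' @export
categorize_folds <- function(ofht, universe) {
  uni <- vapply(universe, function(u) topology_key(u), character(1))
  val <- stats::setNames(ofht$ofht, ofht$topology)
  o <- unname(val[uni])
  o[is.na(o)] <- 0
  category <- ifelse(o >= 3, "superfold", ifelse(o > 0, "normal", "unobserved"))
  tab <- data.frame(topology = uni, ofht = o, category = category,
                    stringsAsFactors = FALSE)
  outside <- ofht[!(ofht$topology %in% uni), , drop = FALSE]
  if (nrow(outside))
    warning("observed topologies outside the universe: ",
            paste(outside$topology, collapse = ", "), call. = FALSE)
  list(table = tab[order(-tab$ofht, tab$topology), ],
       counts = c(superfold = sum(category == "superfold"),
                  normal = sum(category == "normal"),
                  unobserved = sum(category == "unobserved")),
       outside_universe = outside)
}

#' OFHT of reverse-asymmetric frustrated pairs
#'
#' For every unordered pair \{T, reverse(T)\} in the universe in which
#' exactly one member has no frustrated alpha-beta-unit pairing, reports the
#' two OFHT values with the frustration-free member first and whether it
#' dominates (ties count as domination).
#'
#' @param ofht `ofht_table`.
#' @param universe List of occupant vectors, typically the clash-free set.
#' @return Data frame with columns `topology_free`, `topology_frustrated`,
#'   `ofht_free`, `ofht_frustrated`, `free_dominates`.
#' @export
reverse_pair_report <- function(ofht, universe) {
  uni <- lapply(universe, function(u)
    if (is.character(u)) canonicalize_topology(parse_topology(u))
    else canonicalize_topology(u))
  keys <- vapply(uni, function(u) format_topology(u, "ascii"), character(1))
  val <- stats::setNames(ofht$ofht, ofht$topology)
  getv <- function(k) if (k %in% names(val)) unname(val[[k]]) else 0
  seen <- character(0)
  rows <- list()
  for (i in seq_along(uni)) {
    t <- uni[[i]]; tk <- keys[i]
    r <- reverse_topology(t); rk <- format_topology(r, "ascii")
    if (tk == rk || tk %in% seen || !(rk %in% keys)) next
    seen <- c(seen, tk, rk)
    ft <- count_fabp(t); fr <- count_fabp(r)
    if ((ft == 0L) == (fr == 0L)) next
    free <- if (ft == 0L) tk else rk
    fru <- if (ft == 0L) rk else tk
    rows[[length(rows) + 1L]] <- data.frame(
      topology_free = free, topology_frustrated = fru,
      ofht_free = getv(free), ofht_frustrated = getv(fru),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(topology_free = character(0), topology_frustrated = character(0),
               ofht_free = numeric(0), ofht_frustrated = numeric(0))
  out$free_dominates <- out$ofht_free >= out$ofht_frustrated
  out
}

# ---- topology derivation from sheet records --------------------------------

#' Construct a domain sheet record
#'
#' An abstract description of one domain's beta-sheet, sufficient to derive
#' its topology: per-strand sheet positions and orientations in sequence
#' order, hydrogen-bonded strand pairings with relative orientation, barrel
#' flag, number of sheets among the domain's strands, and the inter-strand
#' loop lengths.
#'
#' @param domain_id Identifier.
#' @param strands Data frame with columns `index` (sequence order 1..n),
#'   `position` (sheet position 1..n), `orientation` (`"up"`/`"down"`).
#' @param pairings Data frame with columns `a`, `b` (strand indices) and
#'   `relative` (`"parallel"`/`"antiparallel"`); defaults to the adjacent
#'   sheet positions, all parallel.
#' @param barrel Is the sheet closed into a barrel?
#' @param sheet_count Number of distinct sheets among the domain's strands.
#' @param loops Residue counts of the n-1 inter-strand loops.
#' @return List of class `sheet_record`.
#' @export
sheet_record <- function(domain_id, strands, pairings = NULL, barrel = FALSE,
                         sheet_count = 1L, loops = NULL) {
  if (!all(c("index", "position", "orientation") %in% names(strands)))
    stop("strands needs columns index, position, orientation", call. = FALSE)
  n <- nrow(strands)
  if (!setequal(strands$index, seq_len(n)) ||
      !setequal(strands$position, seq_len(n)))
    stop("strand indices and positions must each cover 1..n", call. = FALSE)
  if (is.null(pairings)) {
    pos2strand <- strands$index[order(strands$position)]
    pairings <- data.frame(a = pos2strand[-n], b = pos2strand[-1L],
                           relative = "parallel", stringsAsFactors = FALSE)
  }
  if (!all(c(pairings$a, pairings$b) %in% strands$index))
    stop("pairings reference undeclared strands", call. = FALSE)
  if (is.null(loops)) loops <- rep(5L, n - 1L)
  structure(list(domain_id = domain_id, strands = strands,
                 pairings = pairings, barrel = isTRUE(barrel),
                 sheet_count = as.integer(sheet_count),
                 loops = as.numeric(loops)),
            class = "sheet_record")
}

#' Derive a topology from a sheet record
#'
#' Applies the four extraction criteria for pure parallel sheets:
#' (i) every hydrogen-bonded pair of sheet-adjacent strands is parallel;
#' (ii) the sheet is open, not a barrel; (iii) the domain's strands form a
#' single sheet; (iv) every loop between consecutive strands is shorter than
#' 100 residues.  Records passing all four yield the canonical occupant
#' string; failures are typed by the first criterion violated.
#'
#' @param record A [sheet_record()].
#' @param max_loop Loop length cutoff (residues; default 100).
#' @return List of class `topology_derivation`: `accepted`, `topology`
#'   (arrow-dialect string or `NA`), `criterion` (`NA` or one of
#'   `"i"`..`"iv"`).
#' @export
derive_topology <- function(record, max_loop = 100) {
  if (!inherits(record, "sheet_record"))
    stop("record must be a sheet_record", call. = FALSE)
  reject <- function(crit) structure(
    list(accepted = FALSE, topology = NA_character_, criterion = crit,
         domain_id = record$domain_id),
    class = "topology_derivation")

  pos <- stats::setNames(record$strands$position, record$strands$index)
  adjacent <- abs(pos[as.character(record$pairings$a)] -
                  pos[as.character(record$pairings$b)]) == 1L
  if (any(adjacent & record$pairings$relative != "parallel")) return(reject("i"))
  if (record$barrel) return(reject("ii"))
  if (record$sheet_count != 1L) return(reject("iii"))
  if (any(record$loops >= max_loop)) return(reject("iv"))
  if (any(record$strands$orientation != "up")) return(reject("i"))

  occupants <- record$strands$index[order(record$strands$position)]
  structure(list(accepted = TRUE,
                 topology = format_topology(canonicalize_topology(occupants)),
                 criterion = NA_character_, domain_id = record$domain_id),
            class = "topology_derivation")
}

#' Read / write sheet records as JSON
#'
#' @param path File path (a JSON array of record objects).
#' @param records List of [sheet_record()]s.
#' @return `read_sheet_records`: list of records; `write_sheet_records`:
#'   the path, invisibly.
#' @export
read_sheet_records <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  n <- length(raw$domain_id)
  lapply(seq_len(n), function(k) {
    sheet_record(domain_id = raw$domain_id[[k]],
                 strands = raw$strands[[k]],
                 pairings = raw$pairings[[k]],
                 barrel = raw$barrel[[k]],
                 sheet_count = raw$sheet_count[[k]],
                 loops = raw$loops[[k]])
  })
}

#' @rdname read_sheet_records
#' @export
write_sheet_records <- function(records, path) {
  payload <- list(
    domain_id = vapply(records, `[[`, character(1), "domain_id"),
    strands = lapply(records, `[[`, "strands"),
    pairings = lapply(records, `[[`, "pairings"),
    barrel = vapply(records, `[[`, logical(1), "barrel"),
    sheet_count = vapply(records, `[[`, integer(1), "sheet_count"),
    loops = lapply(records, `[[`, "loops")
  )
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
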