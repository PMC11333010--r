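# 2D lattice HP model with sequence-independent penalty motifs.
#
# The heavy lifting (exhaustive walk enumeration, per-walk annotation and the
# full designability scan over all 2^L HP sequences) is in compiled code; the
# functions here define the motif templates, validate their frustration
# properties, and provide conformation-level operations in plain R so that
# the compiled annotation has an independent counterpart to be checked
# against.

STEP_DX <- c(1L, 0L, -1L, 0L)
STEP_DY <- c(0L, 1L, 0L, -1L)

#' Energy parameters for the penalty-augmented HP model
#'
#' @param eps_hh Reward per hydrophobic-hydrophobic contact (energy units,
#'   enters negatively).
#' @param eps_penalty Penalty per occurrence of an unfavourable local motif.
#' @return Named list of class `energy_params`.
#' @export
energy_params <- function(eps_hh = 1.0, eps_penalty = 2.0) {
  if (eps_hh < 0 || eps_penalty < 0)
    stop("energy parameters must be non-negative", call. = FALSE)
  structure(list(eps_hh = eps_hh, eps_penalty = eps_penalty),
            class = "energy_params")
}

# ---- motif templates -------------------------------------------------------

points_from_turns <- function(turns) {
  n <- nchar(turns) + 2L
  pts <- matrix(0L, n, 2L)
  pts[2L, ] <- c(1L, 0L)
  d <- 0L
  tv <- strsplit(turns, "")[[1L]]
  for (i in seq_len(n - 2L)) {
    d <- switch(tv[i], S = d, L = (d + 1L) %% 4L, R = (d + 3L) %% 4L)
    pts[i + 2L, ] <- pts[i + 1L, ] + c(STEP_DX[d + 1L], STEP_DY[d + 1L])
  }
  pts
}

turns_from_points <- function(points) {
  steps <- diff(points)
  codes <- apply(steps, 1L, function(s) {
    i <- which(STEP_DX == s[1L] & STEP_DY == s[2L])
    if (!length(i)) stop("points are not a unit-step chain", call. = FALSE)
    i - 1L
  })
  if (length(codes) < 2L) return("")
  d <- (diff(codes)) %% 4L
  paste(c("S", "L", NA, "R")[d + 1L], collapse = "")
}

# The 8 point-group images (4 rotations x optional reflection) of a path,
# each translated to start at the origin, deduplicated.
motif_images <- function(points) {
  rot <- function(p) cbind(-p[, 2L], p[, 1L])
  refl <- function(p) cbind(p[, 1L], -p[, 2L])
  imgs <- list()
  p <- points
  for (r in 1:4) {
    p <- rot(p)
    imgs <- c(imgs, list(p), list(refl(p)))
  }
  imgs <- lapply(imgs, function(m) sweep(m, 2L, m[1L, ]))
  keys <- vapply(imgs, function(m) paste(t(m), collapse = ","), character(1))
  imgs[!duplicated(keys)]
}

#' Construct a motif template
#'
#' @param id Template identifier.
#' @param path Integer matrix of relative lattice coordinates (one row per
#'   residue, N- to C-terminal order) forming a short self-avoiding walk.
#' @param anchor `"any"` to count the motif at every chain window,
#'   `"not_c_terminal"` to skip an occurrence flush with the C-terminal end
#'   of the chain (used for the FLS, which is not frustrated when nothing
#'   follows it).
#' @return List of class `motif_template` with the path, its turn string and
#'   the deduplicated point-group images.
#' @export
motif_template <- function(id, path, anchor = c("any", "not_c_terminal")) {
  anchor <- match.arg(anchor)
  path <- matrix(as.integer(path), ncol = 2L)
  if (nrow(path) < 3L) stop("motif path needs at least 3 residues", call. = FALSE)
  steps <- diff(path)
  if (any(abs(steps[, 1L]) + abs(steps[, 2L]) != 1L))
    stop("motif path must take unit steps", call. = FALSE)
  if (anyDuplicated(paste(path[, 1L], path[, 2L])))
    stop("motif path must be self-avoiding", call. = FALSE)
  structure(list(id = id, path = path, turns = turns_from_points(path),
                 images = motif_images(path), anchor = anchor),
            class = "motif_template")
}

#' The unfavourable local structures of the lattice model
#'
#' Returns the three penalty motifs and the frustrated local structure
#' (FLS).  The FLS is the 4-residue motif whose turn string is
#' straight-then-bend (`"SL"` up to mirror): a bend immediately preceded by
#' a straight step.  Its three self-avoiding one-residue C-terminal
#' extensions (`"SLS"`, `"SLL"`, `"SLR"`) are the penalty motifs, so every
#' way of continuing the chain past an FLS is penalised, while an FLS flush
#' with the C-terminal end costs nothing -- the lattice analogue of a
#' frustrated alpha-beta-unit pairing, whose reverse is likewise
#' unfrustrated.  All templates are matched over their 8 point-group images
#' with the chain direction respected.
#'
#' The returned set has already passed [verify_fls_frustration()].
#'
#' @return List of class `lattice_motifs` with elements `penalty` (list of
#'   three `motif_template`s) and `fls` (one `motif_template`), attribute
#'   `validated` set.
#' @export
lattice_motifs <- function() {
  motifs <- structure(list(
    penalty = list(
      motif_template("penalty_A", points_from_turns("SLS")),
      motif_template("penalty_B", points_from_turns("SLL")),
      motif_template("penalty_C", points_from_turns("SLR"))
    ),
    fls = motif_template("FLS", points_from_turns("SL"),
                         anchor = "not_c_terminal")
  ), class = "lattice_motifs")
  report <- verify_fls_frustration(motifs)
  if (!report$ok) stop("internal error: default motif set failed validation")
  attr(motifs, "validated") <- TRUE
  motifs
}

#' Verify the frustration properties of a motif set
#'
#' A candidate motif set is acceptable only if (a) every self-avoiding
#' one-residue C-terminal extension of the FLS contains at least one penalty
#' motif, (b) the FLS itself -- e.g. placed at the chain's C-terminal end --
#' contains none, and (c) the reverse FLS admits at least one one-residue
#' extension on both ends simultaneously that contains none.  Together these
#' make the FLS frustrated and its reverse unfrustrated, mirroring the
#' asymmetry of frustrated alpha-beta-unit pairings under chain reversal.
#'
#' @param motifs A `lattice_motifs` list (elements `penalty`, `fls`).
#' @param stop_on_failure Raise an error naming the failing check instead of
#'   returning a failed report.
#' @return List of class `fls_validation`: `ok` plus per-check details
#'   (`c_extensions`, `fls_clean`, `reverse_extensions`).  When validation
#'   succeeds the input is returned with attribute `validated` in
#'   `$motifs`.
#' @export
verify_fls_frustration <- function(motifs, stop_on_failure = FALSE) {
  fls <- motifs$fls
  pen <- motifs$penalty
  count_pen <- function(points)
    sum(vapply(pen, function(tpl) count_template(points, tpl), integer(1)))

  # (a) every self-avoiding C-terminal extension is penalised
  exts <- extend_walk(fls$path, end = "C")
  a_pen <- vapply(exts, count_pen, integer(1))
  a_ok <- length(exts) > 0L && all(a_pen > 0L)

  # (b) the FLS alone carries no penalty
  b_ok <- count_pen(fls$path) == 0L

  # (c) the reverse FLS extends penalty-free on both ends at once
  rpath <- fls$path[rev(seq_len(nrow(fls$path))), , drop = FALSE]
  both <- list()
  for (n_ext in extend_walk(rpath, end = "N"))
    both <- c(both, extend_walk(n_ext, end = "C"))
  c_pen <- vapply(both, count_pen, integer(1))
  c_ok <- length(both) > 0L && any(c_pen == 0L)

  report <- structure(list(
    ok = a_ok && b_ok && c_ok,
    c_extensions = data.frame(extension = seq_along(exts), n_penalty = a_pen,
                              penalised = a_pen > 0L),
    fls_clean = b_ok,
    reverse_extensions = data.frame(extension = seq_along(both),
                                    n_penalty = c_pen)
  ), class = "fls_validation")
  if (!report$ok && stop_on_failure) {
    fail <- if (!a_ok) {
      paste0("C-terminal extension ", which(a_pen == 0L)[1L],
             " of the FLS contains no penalty motif")
    } else if (!b_ok) {
      "the FLS itself contains a penalty motif"
    } else {
      "no both-end extension of the reverse FLS avoids all penalty motifs"
    }
    stop("motif validation failed: ", fail, call. = FALSE)
  }
  report
}

# All self-avoiding one-residue extensions of a walk at one end.
extend_walk <- function(points, end = c("C", "N")) {
  end <- match.arg(end)
  if (end == "N") points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  tail_pt <- points[nrow(points), ]
  out <- list()
  for (d in 1:4) {
    cand <- tail_pt + c(STEP_DX[d], STEP_DY[d])
    if (any(points[, 1L] == cand[1L] & points[, 2L] == cand[2L])) next
    ext <- rbind(points, cand)
    if (end == "N") ext <- ext[rev(seq_len(nrow(ext))), , drop = FALSE]
    out <- c(out, list(ext))
  }
  out
}

# Occurrences of one template in a conformation by direct geometric matching:
# slide a window of the template's length along the chain and compare the
# origin-translated window against each point-group image.  Identical
# geometric matches reached through different images are counted once
# (images are deduplicated at construction).
count_template <- function(points, template) {
  m <- nrow(template$path)
  n <- nrow(points)
  if (n < m) return(0L)
  cnt <- 0L
  last <- n - m + 1L
  for (j in seq_len(last)) {
    if (template$anchor == "not_c_terminal" && j == last) next
    win <- points[j:(j + m - 1L), , drop = FALSE]
    win <- sweep(win, 2L, win[1L, ])
    for (img in template$images) {
      if (all(win == img)) { cnt <- cnt + 1L; break }
    }
  }
  cnt
}

#' Count penalty and FLS motifs in a conformation
#'
#' @param points Integer matrix of lattice coordinates, one row per residue.
#' @param motifs Validated motif set from [lattice_motifs()] (or a custom
#'   set accepted by [verify_fls_frustration()]).
#' @return Named integer vector `c(n_penalty, n_fls)`.
#' @export
count_motifs <- function(points, motifs = lattice_motifs()) {
  if (!isTRUE(attr(motifs, "validated"))) {
    report <- verify_fls_frustration(motifs, stop_on_failure = TRUE)
  }
  points <- as_conformation(points)
  c(n_penalty = sum(vapply(motifs$penalty, function(tpl)
      count_template(points, tpl), integer(1))),
    n_fls = count_template(points, motifs$fls))
}

# ---- conformations ---------------------------------------------------------

as_conformation <- function(points) {
  points <- matrix(as.integer(points), ncol = 2L)
  if (nrow(points) < 2L) stop("a conformation needs at least 2 residues", call. = FALSE)
  steps <- diff(points)
  if (any(abs(steps[, 1L]) + abs(steps[, 2L]) != 1L))
    stop("consecutive residues must differ by a unit lattice step", call. = FALSE)
  if (anyDuplicated(paste(points[, 1L], points[, 2L])))
    stop("conformation must be self-avoiding", call. = FALSE)
  points
}

#' Canonicalize a conformation
#'
#' Translates the first residue to the origin, rotates the first step onto
#' +x and, if the first off-axis step points into the -y half-plane, mirrors
#' about the x-axis.  Every walk in a symmetry class (4 rotations x optional
#' reflection) maps to the same representative.
#'
#' @param points Integer matrix of lattice coordinates.
#' @return Canonical coordinate matrix.
#' @export
canonicalize_conformation <- function(points) {
  points <- as_conformation(points)
  points <- sweep(points, 2L, points[1L, ])
  s1 <- points[2L, ]
  # rotate first step onto +x
  for (r in 0:3) {
    if (all(s1 == c(1L, 0L))) break
    points <- cbind(points[, 2L], -points[, 1L])
    s1 <- points[2L, ]
  }
  offx <- which(points[, 2L] != 0L)
  if (length(offx) && points[offx[1L], 2L] < 0L)
    points[, 2L] <- -points[, 2L]
  unname(points)
}

#' Reverse a conformation
#'
#' Reverses the residue order (chain direction) and re-canonicalizes.  An
#' involution on canonical forms; the contact map is preserved up to the
#' index relabelling i -> L+1-i, so contact counts and RCO are invariant
#' while motif counts need not be -- that asymmetry is the point of the
#' model.
#'
#' @param points Integer matrix of lattice coordinates.
#' @return Canonical coordinate matrix of the reversed walk.
#' @export
reverse_conformation <- function(points) {
  points <- as_conformation(points)
  canonicalize_conformation(points[rev(seq_len(nrow(points))), , drop = FALSE])
}

#' Contact map of a conformation
#'
#' Non-covalent lattice contacts: residue pairs adjacent on the lattice but
#' not along the chain.  On the square lattice such pairs always have odd
#' sequence separation >= 3; a 16-residue chain has at most 9 contacts.
#'
#' @param points Integer matrix of lattice coordinates.
#' @return Two-column integer matrix of residue index pairs (i < j), ordered
#'   by i then j.
#' @export
contact_map <- function(points) {
  points <- as_conformation(points)
  n <- nrow(points)
  out <- NULL
  for (i in seq_len(max(0L, n - 3L))) {
    j <- seq.int(i + 3L, n, by = 2L)
    adj <- abs(points[j, 1L] - points[i, 1L]) +
           abs(points[j, 2L] - points[i, 2L]) == 1L
    if (any(adj)) out <- rbind(out, cbind(i, j[adj]))
  }
  if (is.null(out)) out <- matrix(integer(0), 0L, 2L)
  dimnames(out) <- NULL
  colnames(out) <- c("i", "j")
  out
}

#' Relative contact order of a conformation
#'
#' RCO = (1 / (L N)) * sum of |i - j| over the N contacts of an L-residue
#' chain; `NA` when the conformation has no contacts.
#'
#' @param points Integer matrix of lattice coordinates.
#' @return Numeric value in (0, 1\], or `NA_real_`.
#' @export
rco <- function(points) {
  points <- as_conformation(points)
  cm <- contact_map(points)
  if (!nrow(cm)) return(NA_real_)
  sum(cm[, 2L] - cm[, 1L]) / (nrow(points) * nrow(cm))
}

#' Energy of an HP sequence on a conformation
#'
#' E = -eps_hh * n_HH + eps_penalty * n_penalty, where n_HH counts contacts
#' whose two residues are both hydrophobic and n_penalty counts penalty
#' motifs (sequence-independent).
#'
#' @param sequence Character string over \{H, P\} of the chain length.
#' @param points Integer matrix of lattice coordinates.
#' @param params [energy_params()].
#' @param motifs Validated motif set; used only when `n_penalty` is `NULL`.
#' @param n_penalty Optional precomputed penalty count for `points`.
#' @return Numeric energy.
#' @export
hp_energy <- function(sequence, points, params = energy_params(),
                      motifs = lattice_motifs(), n_penalty = NULL) {
  points <- as_conformation(points)
  res <- strsplit(toupper(sequence), "")[[1L]]
  if (length(res) != nrow(points))
    stop("sequence length (", length(res), ") does not match chain length (",
         nrow(points), ")", call. = FALSE)
  if (!all(res %in% c("H", "P")))
    stop("sequence must use the H/P alphabet", call. = FALSE)
  if (is.null(n_penalty)) n_penalty <- count_motifs(points, motifs)[["n_penalty"]]
  cm <- contact_map(points)
  n_hh <- if (nrow(cm)) sum(res[cm[, 1L]] == "H" & res[cm[, 2L]] == "H") else 0L
  -params$eps_hh * n_hh + params$eps_penalty * n_penalty
}

# ---- exhaustive enumeration and scan ---------------------------------------

#' Enumerate self-avoiding walks
#'
#' All self-avoiding walks of `length` residues on the square lattice, one
#' canonical representative per symmetry class (4 rotations x optional
#' reflection): 802,075 conformations at the default study length of 16.
#'
#' @param length Chain length (number of residues).
#' @param max_length Resource guard; enumeration grows as ~2.6^L.
#' @return Object of class `saw_set`: list with `length`, `n` and the step
#'   matrix (`n` x `length`-1, step codes 0 = +x, 1 = +y, 2 = -x, 3 = -y).
#' @export
enumerate_saws <- function(length, max_length = 18L) {
  if (length < 2L) stop("chain length must be at least 2", call. = FALSE)
  if (length > max_length)
    stop("refusing enumeration above length ", max_length,
         "; raise `max_length` explicitly if this is intended", call. = FALSE)
  steps <- cpp_enumerate_saws(as.integer(length))
  structure(list(length = as.integer(length), n = nrow(steps), steps = steps),
            class = "saw_set")
}

#' @export
print.saw_set <- function(x, ...) {
  cat("saw_set: ", x$n, " canonical self-avoiding walks of length ",
      x$length, "\n", sep = "")
  invisible(x)
}

#' Extract one conformation from a walk set
#'
#' @param saws A `saw_set`.
#' @param i Walk index (1-based, enumeration order).
#' @return Coordinate matrix of the i-th canonical walk.
#' @export
saw_conformation <- function(saws, i) {
  codes <- saws$steps[i, ] + 1L
  pts <- rbind(c(0L, 0L),
               cbind(cumsum(STEP_DX[codes]), cumsum(STEP_DY[codes])))
  unname(pts)
}

#' Annotate every walk in a set
#'
#' @param saws A `saw_set`.
#' @param motifs Validated motif set.
#' @return Data frame with one row per walk: `n_c` (contacts), `n_penalty`,
#'   `n_fls`, `rco` (`NA` for contact-free walks).
#' @export
annotate_saws <- function(saws, motifs = lattice_motifs()) {
  if (!isTRUE(attr(motifs, "validated")))
    verify_fls_frustration(motifs, stop_on_failure = TRUE)
  pen <- vapply(motifs$penalty, function(tpl) tpl$turns, character(1))
  cpp_annotate_saws(saws$steps, pen, motifs$fls$turns,
                    motifs$fls$anchor == "not_c_terminal")
}

#' Index of each walk's chain-reversed counterpart
#'
#' @param saws A `saw_set`.
#' @return Integer vector r with `r[i]` the index of the canonical form of
#'   walk i reversed; an involution.
#' @export
saw_reverse_index <- function(saws) {
  cpp_reverse_index(saws$steps)
}

eps_scale <- function(params) {
  for (scale in c(1, 10, 100)) {
    eh <- params$eps_hh * scale
    ep <- params$eps_penalty * scale
    if (abs(eh - round(eh)) < 1e-9 && abs(ep - round(ep)) < 1e-9)
      return(list(scale = scale, eh = as.integer(round(eh)),
                  ep = as.integer(round(ep))))
  }
  stop("energy parameters must be expressible in hundredths for exact ",
       "integer tie detection", call. = FALSE)
}

#' Exhaustive designability scan
#'
#' Evaluates E = -eps_hh * n_HH + eps_penalty * n_penalty for every HP
#' sequence of the chain length over every conformation, exactly (integer
#' arithmetic).  A sequence is protein-like when exactly one conformation
#' attains its minimum energy; the designability N_s of a structure is the
#' number of sequences for which it is that unique ground state.
#' Conformations are grouped by contact set with penalty-count
#' multiplicities, so degenerate minima are detected exactly.
#'
#' @param saws A `saw_set` (length <= 16 for the 2^L sequence space).
#' @param params [energy_params()].
#' @param motifs Validated motif set.
#' @param annotations Optional precomputed [annotate_saws()] result.
#' @return Object of class `designability_result`: `n_s` (per-walk),
#'   `protein_like_count`, `min_energy` and `n_min_conformations` (per
#'   sequence, indexed by bitmask + 1 with residue i -> bit i-1, H = 1),
#'   `n_contact_classes`, `params`, `length`.
#' @export
designability_scan <- function(saws, params = energy_params(),
                               motifs = lattice_motifs(), annotations = NULL) {
  if (saws$length > 16L)
    stop("exhaustive sequence scan supports length <= 16", call. = FALSE)
  if (is.null(annotations)) annotations <- annotate_saws(saws, motifs)
  sc <- eps_scale(params)
  res <- cpp_designability_scan(saws$steps, annotations$n_penalty,
                                sc$eh, sc$ep, sc$scale)
  structure(c(res, list(params = params, length = saws$length)),
            class = "designability_result")
}

#' @export
print.designability_result <- function(x, ...) {
  cat("designability scan: L = ", x$length, ", ",
      x$protein_like_count, " protein-like sequences, max N_s = ",
      max(x$n_s), "\n", sep = "")
  invisible(x)
}

#' Sequence bitmask helpers
#'
#' `hp_mask` encodes an H/P string as the integer bitmask used to index the
#' per-sequence vectors of [designability_scan()] (residue i -> bit i-1,
#' H = 1); `mask_hp` decodes it.
#'
#' @param sequence H/P character string.
#' @param mask Integer bitmask.
#' @param length Chain length.
#' @return Integer mask, or character sequence.
#' @export
hp_mask <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  if (!all(res %in% c("H", "P"))) stop("sequence must be over {H, P}", call. = FALSE)
  sum(bitwShiftL(1L, which(res == "H") - 1L))
}

#' @rdname hp_mask
#' @export
mask_hp <- function(mask, length) {
  paste(ifelse(bitwAnd(bitwShiftR(as.integer(mask), seq_len(length) - 1L), 1L) == 1L,
               "H", "P"), collapse = "")
}

#' Designability grid and reversal report
#'
#' Maps all structures, and the highly designable ones, onto the
#' (N_FLS, N_c) grid; also returns the designability histogram and the
#' structure-versus-reverse pairs in which exactly one member is FLS-free.
#'
#' @param annotations [annotate_saws()] result.
#' @param result [designability_scan()] result.
#' @param saws The `saw_set` the annotations refer to (for reversal pairing).
#' @param threshold High-designability cutoff on N_s (default 100).
#' @return List: `grid_all` and `grid_high` (rows N_FLS 0/1/2+, one column
#'   per contact count covering the 6 highest observed values plus an
#'   overflow column for smaller counts), `histogram` (table of N_s over
#'   structures with N_s > 0), `reverse_pairs` (data frame of FLS-free
#'   member vs FLS-containing reverse designabilities), `threshold`.
#' @export
grid_summary <- function(annotations, result, saws, threshold = 100) {
  nc_max <- max(annotations$n_c)
  nc_lo <- max(0L, nc_max - 5L)
  col_edges <- c(-1L, seq(nc_lo, nc_max))
  col_names <- c(paste0("<", nc_lo), as.character(seq(nc_lo, nc_max)))
  fr <- pmin(annotations$n_fls, 2L)
  cc <- cut(annotations$n_c, breaks = c(col_edges, Inf), labels = col_names,
            right = FALSE)
  # `cut` with right = FALSE: intervals [edge, next); last bin absorbs nc_max
  grid_all <- table(factor(fr, levels = 0:2, labels = c("0", "1", "2+")), cc)
  high <- result$n_s >= threshold
  grid_high <- table(factor(fr[high], levels = 0:2, labels = c("0", "1", "2+")),
                     cc[high])
  rev_idx <- saw_reverse_index(saws)
  free <- which(annotations$n_fls == 0L & annotations$n_fls[rev_idx] > 0L)
  reverse_pairs <- data.frame(
    structure = free,
    reverse = rev_idx[free],
    n_s_fls_free = result$n_s[free],
    n_s_fls = result$n_s[rev_idx[free]]
  )
  list(grid_all = unclass(grid_all), grid_high = unclass(grid_high),
       histogram = table(result$n_s[result$n_s > 0L]),
       reverse_pairs = reverse_pairs, threshold = threshold)
}
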