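# Independent oracles used by the unit and acceptance tests.  These
# deliberately re-derive results along different routes from the package
# implementation: literal geometry instead of combinatorial rules, plain
# depth-first search instead of symmetry-reduced enumeration, and a dense
# per-conformation energy matrix instead of the grouped scan.

# -- clash oracle -------------------------------------------------------------
# Draw connection k as a straight segment on its face from (p(k), 1) to
# (p(k+1), 0) and test same-face pairs for proper segment intersection with
# the standard orientation predicate.
oracle_clash_free <- function(topology) {
  p <- order(topology)
  n <- length(p)
  if (n < 3) return(TRUE)
  delta <- diff(p)
  face <- ifelse(delta > 0, "front", "back")
  seg <- lapply(seq_len(n - 1), function(k)
    rbind(c(p[k], 1), c(p[k + 1], 0)))
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  properly_cross <- function(s1, s2) {
    d1 <- orient(s2[1, ], s2[2, ], s1[1, ])
    d2 <- orient(s2[1, ], s2[2, ], s1[2, ])
    d3 <- orient(s1[1, ], s1[2, ], s2[1, ])
    d4 <- orient(s1[1, ], s1[2, ], s2[2, ])
    d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0 && d1 != d2 && d3 != d4
  }
  for (a in seq_len(n - 2)) for (b in seq(a + 1, n - 1)) {
    if (face[a] == face[b] && properly_cross(seg[[a]], seg[[b]])) return(FALSE)
  }
  TRUE
}

# -- self-avoiding-walk oracle ------------------------------------------------
# Enumerate every self-avoiding walk from the origin (all four first step
# directions, no symmetry reduction) and deduplicate by the canonical form.
oracle_enumerate_saws <- function(length) {
  dx <- c(1L, 0L, -1L, 0L); dy <- c(0L, 1L, 0L, -1L)
  found <- new.env(parent = emptyenv())
  pts <- matrix(0L, length, 2)
  rec <- function(i) {
    if (i > length) {
      key <- paste(t(canonicalize_conformation(pts)), collapse = ",")
      assign(key, TRUE, envir = found)
      return(invisible())
    }
    for (d in 1:4) {
      nx <- pts[i - 1, 1] + dx[d]; ny <- pts[i - 1, 2] + dy[d]
      if (any(pts[seq_len(i - 1), 1] == nx & pts[seq_len(i - 1), 2] == ny)) next
      pts[i, ] <<- c(nx, ny)
      rec(i + 1)
    }
  }
  rec(2L)
  sort(ls(found))
}

# -- naive designability oracle ----------------------------------------------
# Dense scan: energy of every (sequence, conformation) pair, one conformation
# at a time, no contact-class grouping.  Energies in scaled integers.
oracle_designability <- function(saws, eps_hh = 1, eps_penalty = 2,
                                 motifs = lattice_motifs()) {
  L <- saws$length
  nseq <- 2^L
  scale <- 10L
  eh <- as.integer(round(eps_hh * scale)); ep <- as.integer(round(eps_penalty * scale))
  masks <- 0:(nseq - 1)
  best <- rep(.Machine$integer.max, nseq)
  cnt <- rep(0, nseq)
  arg <- rep(NA_integer_, nseq)
  for (w in seq_len(saws$n)) {
    pts <- saw_conformation(saws, w)
    cm <- contact_map(pts)
    np <- count_motifs(pts, motifs)[["n_penalty"]]
    nhh <- rep(0L, nseq)
    if (nrow(cm)) for (r in seq_len(nrow(cm))) {
      c_mask <- bitwOr(bitwShiftL(1L, cm[r, 1] - 1L), bitwShiftL(1L, cm[r, 2] - 1L))
      nhh <- nhh + as.integer(bitwAnd(masks, c_mask) == c_mask)
    }
    e <- -eh * nhh + ep * np
    lower <- e < best
    tie <- e == best
    best[lower] <- e[lower]
    cnt[lower] <- 1; arg[lower] <- w
    cnt[tie] <- cnt[tie] + 1; arg[tie] <- NA_integer_
  }
  n_s <- tabulate(arg[cnt == 1], nbins = saws$n)
  list(n_s = n_s, protein_like_count = sum(cnt == 1),
       min_energy = best / scale, n_min_conformations = cnt)
}

# small synthetic classification table with hand-computable OFHT
tiny_ecod_table <- function() {
  data.frame(
    domain_id = sprintf("d%02d", 1:8),
    h_group = c("H1", "H1", "H1", "H1", "H2", "H2", "H2", "H2"),
    f_group = c("F1", "F1", "F2", "F2", "F3", "F3", "F3", "F4"),
    topology = c("213", "213", "213", "123", "132", NA, "132", "213"),
    stringsAsFactors = FALSE
  )
}
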