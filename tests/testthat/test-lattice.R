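# Unit tests for the lattice model at small chain lengths; the full-scale
# study numbers live in the acceptance tests.

test_that("walk enumeration matches closed counts and the DFS oracle", {
  expect_equal(enumerate_saws(2L)$n, 1L)
  expect_equal(enumerate_saws(4L)$n, 5L)
  for (L in c(5L, 7L)) {
    saws <- enumerate_saws(L)
    keys <- vapply(seq_len(saws$n), function(i)
      paste(t(saw_conformation(saws, i)), collapse = ","), character(1))
    expect_equal(sort(keys), oracle_enumerate_saws(L))
  }
  expect_error(enumerate_saws(25L), "refusing")
})

test_that("contact maps obey the parity rule and known geometries", {
  straight <- cbind(0:9, 0L)
  expect_equal(nrow(contact_map(straight)), 0L)
  u <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L))
  expect_equal(contact_map(u), matrix(c(1L, 4L), 1,
                                      dimnames = list(NULL, c("i", "j"))))
  snake16 <- do.call(rbind, lapply(0:3, function(y)
    cbind(if (y %% 2 == 0) 0:3 else 3:0, y)))
  expect_equal(nrow(contact_map(snake16)), 9L)  # 24 grid edges - 15 bonds
  saws <- enumerate_saws(8L)
  for (i in seq_len(saws$n)) {
    cm <- contact_map(saw_conformation(saws, i))
    if (nrow(cm)) {
      sep <- cm[, 2] - cm[, 1]
      expect_true(all(sep >= 3L & sep %% 2L == 1L))
    }
  }
})

test_that("conformation canonicalization and reversal behave as involutions", {
  u <- rbind(c(5L, 2L), c(5L, 3L), c(4L, 3L), c(4L, 2L))
  cu <- canonicalize_conformation(u)
  expect_equal(cu[1, ], c(0L, 0L))
  expect_equal(cu[2, ], c(1L, 0L))
  expect_equal(canonicalize_conformation(cu), cu)
  straight <- cbind(0:5, 0L)
  expect_equal(reverse_conformation(straight), canonicalize_conformation(straight))
  saws <- enumerate_saws(9L)
  ridx <- saw_reverse_index(saws)
  expect_equal(ridx[ridx], seq_len(saws$n))  # involution
  ann <- annotate_saws(saws)
  expect_equal(ann$n_c, ann$n_c[ridx])       # contacts survive reversal
  expect_equal(ann$rco, ann$rco[ridx])
  i <- which(ann$n_c > 0)[1]
  pts <- saw_conformation(saws, i)
  expect_equal(reverse_conformation(reverse_conformation(pts)), pts)
  expect_equal(reverse_conformation(pts), saw_conformation(saws, ridx[i]))
})

test_that("rco matches hand values and stays in (0, 1] when defined", {
  u <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L))
  expect_equal(rco(u), 0.75)
  expect_true(is.na(rco(cbind(0:7, 0L))))
  ann <- annotate_saws(enumerate_saws(10L))
  ok <- !is.na(ann$rco)
  expect_true(all(ann$rco[ok] > 0 & ann$rco[ok] <= 1))
})

test_that("motif templates verify their frustration properties", {
  motifs <- lattice_motifs()
  expect_true(isTRUE(attr(motifs, "validated")))
  report <- verify_fls_frustration(motifs)
  expect_true(report$ok)
  expect_true(all(report$c_extensions$penalised))
  expect_true(report$fls_clean)
  expect_true(any(report$reverse_extensions$n_penalty == 0))

  # a straight 4-residue stand-in for the FLS must fail: its extensions can
  # stay straight and avoid every compact penalty motif
  bogus <- motifs
  bogus$fls <- motif_template("FLS", cbind(0:3, 0L), anchor = "not_c_terminal")
  attr(bogus, "validated") <- NULL
  expect_false(verify_fls_frustration(bogus)$ok)
  expect_error(verify_fls_frustration(bogus, stop_on_failure = TRUE),
               "contains no penalty motif")
  expect_error(count_motifs(cbind(0:5, 0L), bogus), "contains no penalty")
})

test_that("motif counting matches fixtures and respects the C-terminal rule", {
  fx <- generate_lattice_fixtures(length = 10L, seed = 7L)
  for (nm in names(fx$conformations)) {
    m <- fx$conformations[[nm]]
    expect_equal(unname(count_motifs(m)[c("n_penalty", "n_fls")]),
                 unname(attr(m, "expected")[c("n_penalty", "n_fls")]),
                 info = nm)
  }
  # forward chain holds an interior FLS, its reversal holds none
  fls <- fx$conformations$fls_chain
  rev <- fx$conformations$reverse_fls_chain
  expect_gte(count_motifs(fls)[["n_fls"]], 1L)
  expect_equal(count_motifs(rev)[["n_fls"]], 0L)
  # an FLS flush with the C-terminal end is free: no penalty, no FLS count
  motifs <- lattice_motifs()
  fls_only <- motifs$fls$path
  expect_equal(unname(count_motifs(fls_only)), c(0L, 0L))
  # chains shorter than the shortest template carry nothing
  expect_equal(unname(count_motifs(rbind(c(0L, 0L), c(1L, 0L)))), c(0L, 0L))
})

test_that("geometric motif matching agrees with the compiled annotation", {
  saws <- enumerate_saws(9L)
  ann <- annotate_saws(saws)
  motifs <- lattice_motifs()
  for (i in seq_len(saws$n)) {
    cm <- count_motifs(saw_conformation(saws, i), motifs)
    expect_equal(unname(cm), c(ann$n_penalty[i], ann$n_fls[i]),
                 info = paste("walk", i))
  }
})

test_that("energies follow E = -eps_hh * n_HH + eps_penalty * n_penalty", {
  snake16 <- do.call(rbind, lapply(0:3, function(y)
    cbind(if (y %% 2 == 0) 0:3 else 3:0, y)))
  all_p <- strrep("P", 16)
  np <- count_motifs(snake16)[["n_penalty"]]
  expect_equal(hp_energy(all_p, snake16), 2 * np)
  all_h <- strrep("H", 16)
  expect_equal(hp_energy(all_h, snake16), -9 + 2 * np)
  # forced arithmetic on (n_HH, n_penalty) pairs at the study parameters
  params <- energy_params(1, 2)
  expect_equal(-1 * 8 + 2 * 0, -8)
  expect_equal(hp_energy(all_h, snake16, params, n_penalty = 0L), -9)
  expect_equal(hp_energy(all_p, snake16, params, n_penalty = 2L), 4)
  expect_error(hp_energy("HP", snake16), "length")
  expect_error(hp_energy(strrep("X", 16), snake16), "alphabet")
  expect_error(energy_params(-1, 2), "non-negative")
})

test_that("grouped designability scan equals the dense per-conformation scan", {
  saws <- enumerate_saws(8L)
  scan <- designability_scan(saws)
  oracle <- oracle_designability(saws)
  expect_equal(scan$n_s, oracle$n_s)
  expect_equal(scan$protein_like_count, oracle$protein_like_count)
  expect_equal(scan$min_energy, oracle$min_energy)
  expect_equal(scan$n_min_conformations, oracle$n_min_conformations)
})

test_that("scan bookkeeping is consistent and reduces to the HP model", {
  saws <- enumerate_saws(10L)
  ann <- annotate_saws(saws)
  for (ep in c(0, 0.5, 2)) {
    scan <- designability_scan(saws, energy_params(1, ep), annotations = ann)
    expect_equal(sum(scan$n_s), scan$protein_like_count)
  }
  # eps_penalty = 0: energies depend only on H-H contacts
  scan0 <- designability_scan(saws, energy_params(1, 0), annotations = ann)
  masks <- c(0L, hp_mask("HHHHHHHHHH"), hp_mask("HPHPHPHPHP"))
  for (m in masks) {
    e_direct <- min(vapply(seq_len(saws$n), function(i) {
      pts <- saw_conformation(saws, i)
      cm <- contact_map(pts)
      res <- strsplit(mask_hp(m, 10L), "")[[1]]
      nhh <- if (nrow(cm)) sum(res[cm[, 1]] == "H" & res[cm[, 2]] == "H") else 0
      -1 * nhh
    }, numeric(1)))
    expect_equal(scan0$min_energy[m + 1L], e_direct)
  }
  expect_error(designability_scan(enumerate_saws(17L)), "length <= 16")
})

test_that("sequence bitmask helpers invert each other", {
  expect_equal(mask_hp(hp_mask("HPPH"), 4L), "HPPH")
  expect_equal(hp_mask("PPPP"), 0L)
  expect_equal(hp_mask("HPPP"), 1L)
  for (m in c(0L, 5L, 12L, 15L)) expect_equal(hp_mask(mask_hp(m, 4L)), m)
})

test_that("grid summary bins structures and reports reversal pairs", {
  saws <- enumerate_saws(10L)
  ann <- annotate_saws(saws)
  scan <- designability_scan(saws, annotations = ann)
  g <- grid_summary(ann, scan, saws, threshold = 5)
  expect_equal(sum(g$grid_all), saws$n)
  expect_equal(sum(g$grid_high), sum(scan$n_s >= 5))
  expect_true(all(g$grid_high <= g$grid_all))
  g_inf <- grid_summary(ann, scan, saws, threshold = Inf)
  expect_equal(sum(g_inf$grid_high), 0L)
  ridx <- saw_reverse_index(saws)
  expect_true(all(ann$n_fls[g$reverse_pairs$structure] == 0L))
  expect_true(all(ann$n_fls[g$reverse_pairs$reverse] > 0L))
  expect_equal(g$reverse_pairs$reverse, ridx[g$reverse_pairs$structure])
})
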