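test_that("occupation ratios follow the per-family mean", {
  tab <- tiny_ecod_table()
  # H1: F1 fraction 2/2, F2 fraction 1/2 -> OR = 0.75
  expect_equal(compute_or(tab, "213", "H1"), 0.75)
  # unlabeled domains dilute the denominator: H2 F3 has 2/3 with 132
  expect_equal(compute_or(tab, "132", "H2"), mean(c(2 / 3, 0)))
  one_family <- data.frame(domain_id = c("a", "b"), h_group = "H1",
                           f_group = "F1", topology = c("213", "213"))
  expect_equal(compute_or(one_family, "213", "H1"), 1.0)
  expect_equal(compute_or(one_family, "132", "H1"), 0.0)
  expect_error(compute_or(one_family, "213", "H9"), "not found")
})

test_that("OFHT sums occupation ratios over homology groups", {
  tab <- tiny_ecod_table()
  ofht <- compute_ofht(tab)
  expect_equal(ofht$ofht[ofht$topology == "2-1-3"],
               0.75 + mean(c(0, 1)))
  expect_equal(attr(ofht, "n_h_groups"), 2L)
  # complete labelling: total OFHT mass equals the number of H-groups
  full <- tab; full$topology[is.na(full$topology)] <- "123"
  expect_equal(sum(compute_ofht(full)$ofht), 2)
  # permuting domains within families and families within groups is neutral
  shuf <- tab[c(3, 1, 8, 5, 2, 7, 4, 6), ]
  expect_equal(compute_ofht(shuf), compute_ofht(tab), ignore_attr = "row.names")
})

test_that("flip-equivalent labels aggregate on ingest", {
  tab <- data.frame(domain_id = c("a", "b"), h_group = "H1",
                    f_group = c("F1", "F2"),
                    topology = c("312", "2↑1↑3↑"))  # 312 flips to 213
  ofht <- compute_ofht(tab)
  expect_equal(nrow(ofht), 1L)
  expect_equal(ofht$ofht, 1.0)
})

test_that("fold categories partition the universe at the OFHT = 3 boundary", {
  universe <- list(c(1L, 2L, 3L), c(2L, 1L, 3L), c(1L, 3L, 2L))
  ofht <- structure(data.frame(topology = c("1-2-3", "2-1-3", "1-3-2"),
                               ofht = c(3.0, 2.9, 0)),
                    n_h_groups = 5L, class = c("ofht_table", "data.frame"))
  cats <- categorize_folds(ofht, universe)
  expect_equal(unname(cats$counts), c(1L, 1L, 1L))
  tabc <- cats$table
  expect_equal(tabc$category[tabc$topology == "1-2-3"], "superfold")
  expect_equal(tabc$category[tabc$topology == "2-1-3"], "normal")
  expect_equal(tabc$category[tabc$topology == "1-3-2"], "unobserved")
  expect_equal(sum(cats$counts), length(universe))
  # observations outside the universe are retained with a warning
  expect_warning(out <- categorize_folds(ofht, universe[1:2]), "outside")
  expect_equal(out$outside_universe$topology, "1-3-2")
})

test_that("reverse-pair report orders members and flags domination", {
  universe <- enumerate_topologies(3L, 4L)
  universe <- Filter(is_clash_free, universe)
  # plant OFHT so every frustration-free member dominates
  keys <- vapply(universe, function(t) format_topology(t, "ascii"), character(1))
  frustrated <- vapply(universe, function(t) count_fabp(t) > 0L, logical(1))
  ofht <- structure(data.frame(topology = keys,
                               ofht = ifelse(frustrated, 0.1, 5)),
                    class = c("ofht_table", "data.frame"))
  rep <- reverse_pair_report(ofht, universe)
  expect_gt(nrow(rep), 0L)
  expect_true(all(rep$free_dominates))
  expect_true(all(rep$ofht_free >= rep$ofht_frustrated))
  # tie at zero counts as domination
  ofht0 <- structure(data.frame(topology = keys, ofht = 0),
                     class = c("ofht_table", "data.frame"))
  expect_true(all(reverse_pair_report(ofht0, universe)$free_dominates))
  # pair list length matches the set-level pair count
  s <- summarize_topology_set(classify_topologies(universe),
                              clash_free_only = TRUE)
  expect_equal(nrow(rep), s$pair_count)
})

test_that("table I/O round-trips and rejects malformed hierarchies", {
  tab <- tiny_ecod_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ecod_table(tab, path)
  back <- read_ecod_table(path)
  expect_equal(back$topology, c("2-1-3", "2-1-3", "2-1-3", "1-2-3",
                                "1-3-2", NA, "1-3-2", "2-1-3"))
  expect_equal(compute_ofht(back), compute_ofht(tab))
  bad <- tab; bad$f_group[5] <- "F1"  # F1 now spans two H-groups
  expect_error(compute_ofht(bad), "exactly one h_group")
  dup <- tab; dup$domain_id[2] <- dup$domain_id[1]
  expect_error(compute_ofht(dup), "duplicated")
})

test_that("topology derivation applies the four extraction criteria", {
  strands <- data.frame(index = 1:3, position = c(2L, 1L, 3L),
                        orientation = "up")
  rec <- sheet_record("dom1", strands)
  out <- derive_topology(rec)
  expect_true(out$accepted)
  expect_equal(out$topology, "2↑1↑3↑")

  anti <- rec; anti$pairings$relative[1] <- "antiparallel"
  expect_equal(derive_topology(anti)$criterion, "i")
  barrel <- sheet_record("dom2", strands, barrel = TRUE)
  expect_equal(derive_topology(barrel)$criterion, "ii")
  multi <- sheet_record("dom3", strands, sheet_count = 2L)
  expect_equal(derive_topology(multi)$criterion, "iii")
  longloop <- sheet_record("dom4", strands, loops = c(120L, 5L))
  expect_equal(derive_topology(longloop)$criterion, "iv")
  edge99 <- sheet_record("dom5", strands, loops = c(99L, 5L))
  expect_true(derive_topology(edge99)$accepted)
  expect_error(derive_topology(list()), "sheet_record")
  expect_error(sheet_record("x", data.frame(index = c(1, 1, 2),
                                            position = 1:3,
                                            orientation = "up")),
               "cover 1..n")
})

test_that("sheet records round-trip through JSON", {
  recs <- generate_sheet_records(5L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_sheet_records(recs, path)
  back <- read_sheet_records(path)
  expect_length(back, 5L)
  for (k in seq_along(recs)) {
    expect_equal(derive_topology(back[[k]])$topology,
                 derive_topology(recs[[k]])$topology)
  }
})
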