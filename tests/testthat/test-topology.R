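test_that("topology strings parse, format and round-trip in both dialects", {
  expect_equal(parse_topology("2↑1↑3↑"), c(2L, 1L, 3L))
  expect_equal(parse_topology("123"), c(1L, 2L, 3L))
  expect_equal(format_topology(parse_topology("2-1-3")), "2↑1↑3↑")
  expect_equal(format_topology(c(2L, 1L, 3L), "ascii"), "2-1-3")
  # dashed dialect carries wide sheets that the bare dialect cannot
  wide <- c(10L, 1L, seq(2L, 9L))
  expect_equal(parse_topology(format_topology(wide, "ascii")), wide)

  expect_error(parse_topology("213↓"), "down-oriented")
  expect_error(parse_topology("113"), "permutation")
  expect_error(parse_topology("13"), "permutation")
  expect_error(parse_topology("2x3"), "cannot parse")
})

test_that("canonicalization picks the lexicographically smaller flip", {
  expect_equal(canonicalize_topology(c(3L, 1L, 2L)), c(2L, 1L, 3L))
  expect_equal(canonicalize_topology(c(1L, 2L, 3L)), c(1L, 2L, 3L))
  expect_equal(canonicalize_topology(c(2L, 3L, 1L)), c(1L, 3L, 2L))
  # idempotent on every 4-strand topology and invariant under flipping first
  for (t in enumerate_topologies(4L, 4L)) {
    expect_equal(canonicalize_topology(t), t)
    expect_equal(canonicalize_topology(rev(t)), t)
  }
})

test_that("enumeration yields n!/2 canonical classes per strand count", {
  t3 <- enumerate_topologies(3L, 3L)
  expect_equal(length(t3), 3L)
  expect_setequal(vapply(t3, paste, character(1), collapse = ""),
                  c("123", "132", "213"))
  expect_length(enumerate_topologies(4L, 4L), 12L)
  expect_length(enumerate_topologies(3L, 6L), 435L)
  expect_error(enumerate_topologies(3L, 12L), "refusing")
})

test_that("connection geometry assigns faces, spans and long-distance flags", {
  g <- connection_geometry(c(2L, 1L, 3L))
  expect_equal(g$delta, c(-1L, 2L))
  expect_equal(g$face, c("back", "front"))
  g2 <- connection_geometry(c(1L, 2L, 3L))
  expect_equal(g2$delta, c(1L, 1L))
  expect_equal(g2$face, c("front", "front"))
  g3 <- connection_geometry(c(4L, 3L, 2L, 1L, 5L))
  expect_equal(g3$delta[4], 4L)
  expect_true(g3$long_distance[4])
  expect_false(any(g3$long_distance[1:3]))
})

test_that("clash detection agrees with the literal segment-geometry oracle", {
  for (t in enumerate_topologies(3L, 5L)) {
    expect_equal(is_clash_free(t), oracle_clash_free(t),
                 info = paste(t, collapse = ""))
  }
  expect_true(all(vapply(enumerate_topologies(3L, 3L), is_clash_free, logical(1))))
})

test_that("jump and frustrated-pairing counts match hand-derived cases", {
  expect_equal(count_jumps(c(1L, 2L, 3L)), 0L)
  expect_equal(count_jumps(c(2L, 1L, 3L)), 1L)
  expect_equal(count_jumps(c(3L, 2L, 1L, 4L, 5L)), 1L)
  expect_equal(count_fabp(c(2L, 1L, 3L)), 0L)
  expect_equal(count_fabp(c(1L, 3L, 2L)), 1L)
  expect_equal(count_fabp(c(1L, 2L, 3L)), 0L)
})

test_that("chain reversal is a canonical involution preserving invariants", {
  expect_equal(reverse_topology(c(2L, 1L, 3L)), c(1L, 3L, 2L))
  expect_equal(reverse_topology(c(1L, 2L, 3L)), c(1L, 2L, 3L))
  expect_equal(reverse_topology(c(3L, 2L, 1L, 4L, 5L)), c(1L, 2L, 5L, 4L, 3L))
  for (t in enumerate_topologies(5L, 5L)) {
    r <- reverse_topology(t)
    expect_equal(reverse_topology(r), t)
    expect_equal(is_clash_free(r), is_clash_free(t))
    expect_equal(count_jumps(r), count_jumps(t))
  }
})

test_that("betaRCO matches closed-form values and bounds", {
  expect_equal(beta_rco(c(1L, 2L, 3L)), 1 / 3)
  expect_equal(beta_rco(c(2L, 1L, 3L)), 0.5)
  for (n in 3:6) expect_equal(beta_rco(seq_len(n)), 1 / n)
  for (t in enumerate_topologies(5L, 5L)) {
    v <- beta_rco(t)
    expect_gte(v, 1 / 5); expect_lte(v, 4 / 5)
  }
})

test_that("classification assembles edge flags and frustration status", {
  c1 <- classify_topology(c(2L, 1L, 3L))
  expect_true(c1$frustration_free)
  expect_true(c1$c_term_edge)
  expect_false(c1$n_term_edge)
  expect_false(classify_topology(c(1L, 3L, 2L))$frustration_free)
  c3 <- classify_topology(c(1L, 2L, 3L))
  expect_true(c3$n_term_edge && c3$c_term_edge)
})

test_that("classifier outputs are invariant under the left-right flip", {
  for (t in enumerate_topologies(5L, 5L)) {
    a <- classify_topology(t)
    b <- classify_topology(rev(t))  # canonicalized internally to the same class
    expect_equal(a, b)
    # and field-wise on the raw (non-canonical) representative
    expect_equal(count_jumps(rev(t)), count_jumps(t))
    expect_equal(count_fabp(rev(t)), count_fabp(t))
    expect_equal(is_clash_free(rev(t)), is_clash_free(t))
    expect_equal(beta_rco(rev(t)), beta_rco(t))
  }
})

test_that("set summaries respect reversal closure and partition the grid", {
  cls <- classify_topologies(enumerate_topologies(3L, 5L))
  s <- summarize_topology_set(cls, clash_free_only = TRUE)
  # reversal-closed set: N- and C-terminal edge fractions coincide
  expect_equal(unname(s$edge_count["n_term"]), unname(s$edge_count["c_term"]))
  expect_equal(sum(s$grid), s$n_topologies)
  empty <- summarize_topology_set(cls, clash_free_only = TRUE, max_jumps = -1)
  expect_equal(empty$n_topologies, 0L)
  expect_equal(sum(empty$grid), 0L)
})

test_that("classification tables write with the documented column order", {
  cls <- classify_topologies(enumerate_topologies(3L, 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology_table(cls, path)
  back <- read.delim(path)
  expect_equal(names(back)[1:3], c("topology", "n_strands", "clash_free"))
  expect_equal(nrow(back), 3L)
})
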