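test_that("TSV reader validates rather than repairs", {
  ok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# reaction: toy", "1.0\t10", "2.0\t20"), ok)
  tab <- read_xs_table(ok)
  expect_equal(tab$valid_range, c(1, 2))
  expect_equal(tab$reaction_id, "toy")

  bad_order <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("2.0\t20", "1.0\t10"), bad_order)
  expect_error(read_xs_table(bad_order), "ascending")

  bad_neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1.0\t10", "2.0\t-5"), bad_neg)
  expect_error(read_xs_table(bad_neg), ">= 0")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only comments", empty)
  expect_error(read_xs_table(empty), "empty")
})

test_that("write-then-read round trip preserves values bit-exactly", {
  tab <- cross_section_table(c(0.6, 1.234567890123, 40),
                             c(1400, 987.654321098765, 45), "toy")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_xs_table(tab, f)
  rt <- read_xs_table(f)
  expect_identical(rt$energies, tab$energies)
  expect_identical(rt$sigma, tab$sigma)
  expect_identical(rt$reaction_id, "toy")
})

test_that("lin-lin lookup: exact at nodes, interpolates, zero outside", {
  tab <- cross_section_table(c(1, 2), c(10, 30))
  expect_equal(xs_lookup(tab, 1.5), 20)
  expect_equal(xs_lookup(tab, c(1, 2)), c(10, 30))
  expect_equal(xs_lookup(tab, 0.5), 0)
  expect_warning(above <- xs_lookup(tab, 3), "high-energy tail")
  expect_equal(above, 0)
  expect_error(xs_lookup(tab, -1), ">= 0")
  # continuity across the validity range
  e <- seq(1, 2, length.out = 201)
  expect_true(all(abs(diff(xs_lookup(tab, e))) < 0.2))
})

test_that("packaged fusion table anchors at 1400 mb for 600-keV protons", {
  tab <- b11_fusion_xs()
  expect_equal(xs_lookup(tab, 0.6), 1400)
  expect_equal(tab$valid_range, c(0.6, 40))
  expect_equal(tab$reaction_id, "11B(p,aa)a")
})

test_that("1/v model follows the inverse-velocity law", {
  m <- one_over_v_model()
  expect_equal(one_over_v_xs(m, 0.0253), 3837)
  expect_equal(one_over_v_xs(m, 4 * 0.0253), 3837 / 2)
  expect_equal(one_over_v_xs(m, 0.1), 1929.98, tolerance = 1e-5)
  e <- 10 ^ seq(-4, 6, length.out = 50)
  expect_equal(one_over_v_xs(m, e) * sqrt(e),
               rep(3837 * sqrt(0.0253), 50), tolerance = 1e-12)
  expect_error(one_over_v_xs(m, 0), "> 0")
  expect_error(one_over_v_model(sigma0 = -1))
})

test_that("group collapse evaluates sigma at bin midpoints", {
  grid <- energy_grid(0.1, 0L, 100L)
  mids <- grid_midpoints(grid)
  const <- cross_section_table(c(0, 10), c(100, 100))
  expect_equal(group_collapse(const, grid),
               ifelse(mids <= 10, 100, 0))   # last midpoint 10.05 is outside
  lin <- cross_section_table(c(0, 10), c(0, 100))
  mid <- grid_midpoints(grid)
  expect_equal(group_collapse(lin, grid)[mid <= 10], mid[mid <= 10] * 10)
  below <- cross_section_table(c(50, 60), c(1, 1))
  expect_equal(group_collapse(below, grid), rep(0, 101))
})

test_that("collapse commutes with scaling and 1/v collapse is in mb", {
  grid <- energy_grid(0.1, 0L, 50L)
  tab <- cross_section_table(c(0.5, 3, 5), c(10, 40, 20))
  tab3 <- cross_section_table(tab$energies, 3 * tab$sigma)
  expect_equal(group_collapse(tab3, grid), 3 * group_collapse(tab, grid))
  g1 <- log_energy_grid(c(2.53e-8 / 1.1, 2.53e-8 * 1.1), 1L)
  expect_equal(group_collapse(one_over_v_model(), g1), 3837e3)
})
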