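test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(31)
  for (i in 1:25) {
    nr <- sample(8:64, 1); nc <- sample(8:64, 1)
    bw <- matrix(runif(nr * nc) < runif(1, 0.2, 0.6), nr, nc)
    for (conn in c(4L, 8L)) {
      got <- label_components(bw, conn)
      want <- flood_fill_label(bw, conn)
      # same partition: component count and matching pixel groupings
      expect_equal(max(got), max(want))
      expect_true(all((got > 0) == (want > 0)))
      if (max(got) > 0) {
        # labels must induce the identical partition of foreground
        key <- paste(got[bw], want[bw])
        expect_equal(length(unique(key)), max(got))
      }
    }
  }
})

test_that("diagonal touching merges under 8- but not 4-connectivity", {
  bw <- matrix(FALSE, 4, 4)
  bw[1, 1] <- bw[2, 2] <- TRUE
  expect_equal(max(label_components(bw, 8L)), 1L)
  expect_equal(max(label_components(bw, 4L)), 2L)
})

test_that("labelling agrees with EBImage on 4-connectivity", {
  skip_if_not_installed("EBImage")
  set.seed(32)
  for (i in 1:5) {
    bw <- matrix(runif(40 * 40) < 0.4, 40, 40)
    got <- max(label_components(bw, 4L))
    ref <- max(EBImage::bwlabel(bw * 1))
    expect_equal(got, ref)
  }
})

test_that("particle counting applies threshold, size filter and centroid assignment", {
  mask <- matrix(0L, 20, 20)
  mask[2:10, 2:10] <- 1L
  mask[12:19, 12:19] <- 2L
  plane <- matrix(0, 20, 20)
  plane[3:5, 3:5] <- 200          # 9 px in cell 1 -> counted
  plane[13:14, 13:14] <- 200      # 4 px in cell 2 -> below min_area 5
  plane[16:18, 16:17] <- 3        # sub-threshold -> ignored
  p <- pla_params(threshold_low = 6, min_area = 5)
  counts <- count_particles_plane(plane, mask, p)
  expect_equal(counts, c(`1` = 1L, `2` = 0L))
  # all-zero plane counts nothing
  expect_equal(count_particles_plane(matrix(0, 20, 20), mask, p),
               c(`1` = 0L, `2` = 0L))
  # empty mask warns and returns an empty mapping
  expect_warning(out <- count_particles_plane(plane, matrix(0L, 20, 20), p),
                 "no cells")
  expect_length(out, 0L)
})

test_that("particles whose centroid falls on background are discarded", {
  mask <- matrix(0L, 10, 10)
  mask[1:10, 1:4] <- 1L  # blob straddles the border, centroid outside
  plane <- matrix(0, 10, 10)
  plane[4:6, 3:8] <- 200  # centroid at column 5.5 -> background
  counts <- count_particles_plane(plane, mask, pla_params())
  expect_equal(counts, c(`1` = 0L))
})

test_that("raising threshold or min_area never increases any count", {
  set.seed(33)
  mask <- matrix(1L, 32, 32)
  plane <- matrix(sample(0:40, 32 * 32, replace = TRUE), 32, 32)
  base <- count_particles_plane(plane, mask,
                                pla_params(threshold_low = 6, min_area = 5))
  higher_t <- count_particles_plane(plane, mask,
                                    pla_params(threshold_low = 10,
                                               min_area = 5))
  bigger_a <- count_particles_plane(plane, mask,
                                    pla_params(threshold_low = 6,
                                               min_area = 10))
  expect_lte(sum(higher_t), sum(base))
  expect_lte(sum(bigger_a), sum(base))
})

test_that("PLA scores sum per-plane counts and ignore plane order", {
  layout <- matrix(c(1L, 0L, 2L,
                     0L, 3L, 1L), nrow = 3)  # 3 cells x 2 planes
  sim <- simulate_zstack(layout, dim = c(96L, 96L), seed = 5)
  tab <- pla_score(sim$stack, sim$mask, pla_params())
  expect_equal(unname(pla_scores(tab)), unname(rowSums(layout)))
  # single plane reduces to count_particles_plane
  one <- pla_score(sim$stack[1], sim$mask, pla_params())
  expect_equal(unname(pla_scores(one)),
               unname(count_particles_plane(sim$stack[[1]], sim$mask,
                                            pla_params())))
  # duplicated plane triples the counts
  tri <- pla_score(sim$stack[c(1, 1, 1)], sim$mask, pla_params())
  expect_equal(unname(pla_scores(tri)), 3L * unname(pla_scores(one)))
  # plane order is irrelevant to totals
  rev_tab <- pla_score(rev(sim$stack), sim$mask, pla_params())
  expect_equal(pla_scores(rev_tab), pla_scores(tab))
  # shape mismatch is rejected
  expect_error(pla_score(list(matrix(0, 4, 4)), sim$mask), "mask shape")
})

test_that("synthetic stacks are recovered exactly, for both threshold settings", {
  set.seed(34)
  layout <- matrix(sample(0:3, 4 * 7, replace = TRUE), 4, 7)
  sim <- simulate_zstack(layout, dim = c(128L, 128L), seed = 11)
  for (p in list(pla_params(6, 255, 5), pla_params(10, 255, 5))) {
    tab <- pla_score(sim$stack, sim$mask, p)
    expect_equal(unname(pla_scores(tab)), unname(rowSums(layout)))
  }
})

test_that("z-stacks and masks survive the TIFF round trip", {
  layout <- matrix(c(2L, 1L, 0L, 3L), 2, 2)
  sim <- simulate_zstack(layout, dim = c(64L, 64L), seed = 2)
  zp <- withr::local_tempfile(fileext = ".tif")
  mp <- withr::local_tempfile(fileext = ".tif")
  write_zstack(sim$stack, zp)
  write_cell_mask(sim$mask, mp)
  stack2 <- read_zstack(zp)
  mask2 <- read_cell_mask(mp)
  expect_equal(length(stack2), 2L)
  expect_equal(stack2[[1]], sim$stack[[1]])
  expect_identical(mask2, sim$mask)
  # scoring the reloaded data gives identical results
  tab <- pla_score(stack2, mask2, pla_params())
  expect_equal(unname(pla_scores(tab)), unname(rowSums(layout)))
})
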