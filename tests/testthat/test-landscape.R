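micro_energies <- c(-1, 0.5, 0.7, -0.8) # states 00, 01, 10, 11

test_that("the two-channel worked landscape is mapped exactly", {
  ls <- energy_landscape(micro_energies)
  expect_identical(ls$basins$basin, c(0L, 3L))
  # 01 and 10 both descend to 00 (E = -1 < -0.8)
  expect_equal(ls$basins$size, c(3L, 1L))
  expect_equal(ls$basins$fraction, c(0.75, 0.25))
  expect_true(all(ls$basins$major))
  expect_equal(ls$saddle["0", "3"], 0.5)
  bars <- basin_barriers(ls)
  expect_equal(bars$barrier[bars$from == 0 & bars$to == 3], 1.5)
  expect_equal(bars$barrier[bars$from == 3 & bars$to == 0], 1.3)
})

test_that("a flat landscape yields exactly one basin under the tie rule", {
  expect_identical(find_basins(rep(1, 16)), 0L)
  ls <- energy_landscape(rep(1, 16))
  expect_equal(nrow(ls$basins), 1)
  expect_true(all(ls$states$basin == 0L))
})

test_that("basin states are exactly the fixed points of steepest descent", {
  for (seed in 1:25) {
    e <- random_landscape(4, seed)
    basins <- find_basins(e)
    assignment <- assign_to_basins(e)
    expect_setequal(basins, unique(assignment[basins + 1]))
    fixed <- which(assignment == 0:(15)) - 1L
    expect_setequal(basins, fixed)
    expect_equal(sum(table(assignment)), 16)
  }
})

test_that("basins and assignments match the exhaustive oracle on random landscapes", {
  for (seed in 1:40) {
    e <- random_landscape(4, seed + 100)
    expect_identical(find_basins(e), oracle_basins(e))
    expect_identical(assign_to_basins(e), oracle_assignment(e))
  }
})

test_that("minimax Dijkstra saddles match brute-force simple-path search", {
  for (seed in 1:15) {
    e <- random_landscape(4, seed + 200)
    basins <- find_basins(e)
    if (length(basins) < 2) next
    saddle <- saddle_energies(e, basins)
    for (a in seq_along(basins)) {
      expect_equal(saddle[a, a], e[basins[a] + 1])
      for (b in seq_along(basins)) {
        if (a < b) {
          expect_equal(saddle[a, b], oracle_minimax(e, basins[a], basins[b]))
        }
      }
    }
  }
})

test_that("saddle matrix satisfies the bound and ultrametric-like properties", {
  for (seed in 1:10) {
    e <- random_landscape(5, seed + 300)
    basins <- find_basins(e)
    if (length(basins) < 3) next
    s <- saddle_energies(e, basins)
    eb <- e[basins + 1]
    for (a in seq_along(basins)) {
      for (b in seq_along(basins)) {
        expect_gte(s[a, b], max(eb[a], eb[b]))
        for (c in seq_along(basins)) {
          expect_lte(s[a, c], max(s[a, b], s[b, c]) + 1e-12)
        }
      }
    }
  }
})

test_that("single-basin landscapes give an empty saddle matrix with a warning", {
  # energies increasing with code: every state descends towards code 0
  e <- sort(random_landscape(3, 1))
  expect_identical(find_basins(e), 0L)
  expect_warning(s <- saddle_energies(e), "fewer than two")
  expect_equal(dim(s), c(0, 0))
})

test_that("major/minor classification takes the two lowest-energy basins", {
  # three basins at energies (-5, -4, -1): first two are major
  found <- FALSE
  for (seed in 1:50) {
    e <- random_landscape(4, seed + 400)
    ls <- energy_landscape(e)
    if (nrow(ls$basins) >= 3) {
      expect_identical(which(ls$basins$major), 1:2)
      expect_equal(ls$basins$energy, sort(ls$basins$energy))
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # micro example: majors are 00 and 11
  expect_identical(major_basins(energy_landscape(micro_energies)), c(0L, 3L))
})

test_that("dendrogram merges follow single linkage on saddle levels", {
  ls <- energy_landscape(micro_energies)
  d <- build_dendrogram(ls)
  expect_equal(d$hclust$height, 0.5)
  expect_equal(sort(as.integer(d$labels)), c(0L, 3L))
  nwk <- dendrogram_newick(d)
  expect_match(nwk, "^\\(.*\\);$")
  # branch length = merge saddle minus basin energy
  expect_match(nwk, "S0:1.5", fixed = TRUE)
  expect_match(nwk, "S3:1.3", fixed = TRUE)

  # three-leaf hand agglomeration: s(ab)=1 < s(ac)=s(bc)=2
  fake <- structure(
    list(
      states = NULL, n = 2L,
      basins = tibble::tibble(basin = c(1L, 2L, 3L), energy = c(-3, -2.5, -2),
                              size = 1L, fraction = 1 / 3, major = c(TRUE, TRUE, FALSE)),
      saddle = matrix(c(-3, 1, 2, 1, -2.5, 2, 2, 2, -2), 3, 3,
                      dimnames = list(1:3, 1:3))
    ),
    class = "energy_landscape"
  )
  d3 <- build_dendrogram(fake)
  expect_equal(d3$hclust$height, c(1, 2))
  # leaf count equals basin count
  expect_equal(length(d3$hclust$order), 3)
})

test_that("landscape profiles start at the basin energy and rise at radius one", {
  m <- planted6()
  ls <- energy_landscape(m)
  for (b in ls$basins$basin) {
    prof <- landscape_profile(ls, b)
    expect_equal(prof$depth[prof$radius == 0], ls$basins$energy[ls$basins$basin == b])
    if (any(prof$radius == 1)) {
      expect_lt(prof$depth[prof$radius == 0], prof$depth[prof$radius == 1])
    }
    expect_equal(sum(prof$n_states), ls$basins$size[ls$basins$basin == b])
  }
  expect_error(landscape_profile(ls, 999), "not a basin")
})

test_that("basin fractions sum to one on random landscapes", {
  for (seed in 1:10) {
    ls <- energy_landscape(random_landscape(5, seed + 500))
    expect_equal(sum(ls$basins$fraction), 1)
    expect_equal(sum(ls$basins$size), 32)
  }
})
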