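# Landscape harness for dynamics tests: n = 3, two major basins with known
# clusters, built from explicit energies so cluster membership is hand-checkable.
dyn_landscape <- function() {
  # states 0..7; major basins at 0 (cluster {0,1,2,4}) and 3 (cluster
  # {3,6,7}), plus a shallow minor basin at 5
  e <- c(-2, 0.2, 0.4, -1.5, 0.6, -0.1, 0.3, 0.1)
  ls <- energy_landscape(e)
  stopifnot(identical(major_basins(ls), c(0L, 3L)))
  ls
}

test_that("the six-point worked dynamics trace is counted exactly", {
  ls <- dyn_landscape()
  assignment <- ls$states$basin
  a1 <- 0L
  a2 <- 3L
  p1 <- setdiff(which(assignment == a1) - 1L, a1) # non-basin states of P1
  p2 <- setdiff(which(assignment == a2) - 1L, a2)
  s <- c(a1, a1, p1[1], a2, a2, p2[1])
  r <- transition_and_staying_rates(tibble::tibble(state = s), ls)
  expect_equal(r$sr_major, 2 / 6)
  expect_equal(r$sr_peripheral, 2 / 6)
  expect_equal(r$lingering, 2 / 3)
  expect_equal(r$tr_peripheral, 1 / 6)
  expect_equal(r$tr_major, 0)
  expect_equal(r$traveling, 0)
  expect_true(r$traveling_defined)
})

test_that("boundary sequences behave as specified", {
  ls <- dyn_landscape()
  # constant series at the deepest basin
  t_len <- 37
  r <- transition_and_staying_rates(rep(0L, t_len), ls)
  expect_equal(r$sr_major, (t_len - 1) / t_len)
  expect_equal(r$lingering, (t_len - 1) / t_len)
  expect_equal(r$tr_major + r$tr_peripheral + r$sr_peripheral, 0)
  expect_false(r$traveling_defined)
  expect_true(is.na(r$traveling))

  # alternating major basins: everything is a transition
  r2 <- transition_and_staying_rates(c(0L, 3L, 0L, 3L), ls)
  expect_equal(r2$tr_major, 3 / 4)
  expect_equal(r2$tr_peripheral, 3 / 4)
  expect_equal(r2$traveling, 1)
  expect_equal(r2$lingering, 0)
})

test_that("pair counts are conserved and ordered across random series", {
  ls <- dyn_landscape()
  assignment <- ls$states$basin
  cl <- ifelse(assignment %in% c(0L, 3L), assignment, NA_integer_)
  set.seed(71)
  for (rep in 1:20) {
    t_len <- sample(10:200, 1)
    s <- sample(0:7, t_len, replace = TRUE)
    r <- transition_and_staying_rates(s, ls)
    # major-basin transitions are a subset of cross-cluster transitions
    expect_lte(r$tr_major, r$tr_peripheral)
    expect_equal(r$lingering, r$sr_major + r$sr_peripheral)
    # conservation: all categorized pairs plus pairs touching minor clusters
    c0 <- cl[s[-t_len] + 1]
    c1 <- cl[s[-1] + 1]
    minor_pairs <- sum(is.na(c0) | is.na(c1))
    total <- r$sr_major + r$sr_peripheral + r$tr_peripheral + minor_pairs / t_len
    expect_equal(total, (t_len - 1) / t_len)
  }
})

test_that("first-passage mode counts completed basin-to-basin episodes", {
  ls <- dyn_landscape()
  p1 <- 1L # in cluster of 0
  p2 <- 7L # in cluster of 3
  minor <- 5L
  # 0 ... 3: one completed episode even with peripheral states in between
  s <- c(0L, p1, p1, 3L, p2, 0L)
  r <- transition_and_staying_rates(s, ls, mode = "first_passage")
  expect_equal(r$tr_major, 2 / 6) # 0 -> 3 and 3 -> 0
  # direct mode sees no adjacent basin pair
  rd <- transition_and_staying_rates(s, ls, mode = "direct")
  expect_equal(rd$tr_major, 0)
  # strict mode: a minor-cluster visit voids the episode
  s2 <- c(0L, minor, 3L)
  r_loose <- transition_and_staying_rates(s2, ls, mode = "first_passage")
  r_strict <- transition_and_staying_rates(s2, ls,
    mode = "first_passage", first_passage_strict = TRUE
  )
  expect_equal(r_loose$tr_major, 1 / 3)
  expect_equal(r_strict$tr_major, 0)
})

test_that("basin frequencies cover all basins and sum to one per participant", {
  ls <- dyn_landscape()
  set.seed(72)
  df <- tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 50),
    state = sample(0:7, 100, replace = TRUE)
  )
  f <- basin_frequency(df, ls)
  expect_equal(nrow(f), 2 * nrow(ls$basins))
  sums <- dplyr::summarise(dplyr::group_by(f, participant_id), s = sum(frequency))
  expect_equal(sums$s, c(1, 1))
  # hand-checked sequence: basin sequence B1 B1 B2 B1 -> 0.75 / 0.25
  f2 <- basin_frequency(c(0L, 1L, 3L, 2L), ls)
  expect_equal(f2$frequency[f2$basin == 0], 0.75)
  expect_equal(f2$frequency[f2$basin == 3], 0.25)
  # exact-state counting is an option
  f3 <- basin_frequency(c(0L, 1L, 3L, 2L), ls, count = "basin_state")
  expect_equal(f3$frequency[f3$basin == 0], 0.25)
})

test_that("long exact samples occupy clusters with their Boltzmann mass", {
  m <- planted6()
  ls <- energy_landscape(m)
  bd <- boltzmann_distribution(m)
  t_len <- 40000
  s <- sample_states(m, t_len, "exact", seed = 73)
  f <- basin_frequency(s, ls)
  for (b in ls$basins$basin) {
    mass <- sum(bd$probability[ls$states$basin == b])
    se <- sqrt(mass * (1 - mass) / t_len)
    expect_lt(abs(f$frequency[f$basin == b] - mass), 3.5 * se + 1e-12)
  }
})

test_that("cohort metrics respect participant boundaries and input order", {
  ls <- dyn_landscape()
  # two constant participants: no cross-participant pair may be counted
  df <- tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 10),
    time = rep(1:10, 2),
    state = rep(c(0L, 3L), each = 10)
  )
  out <- cohort_dynamics(df, ls)
  expect_equal(nrow(out), 2)
  expect_equal(out$tr_major, c(0, 0))
  expect_equal(out$sr_major, c(0.9, 0.9))
  # permuting participant blocks leaves each participant's metrics unchanged
  df_perm <- dplyr::bind_rows(
    dplyr::filter(df, participant_id == "p2"),
    dplyr::filter(df, participant_id == "p1")
  )
  out_perm <- cohort_dynamics(df_perm, ls)
  expect_identical(
    dplyr::arrange(out, participant_id),
    dplyr::arrange(out_perm, participant_id)
  )
})

test_that("stronger coupling raises lingering scores in a planted contrast", {
  reps <- 12
  ps <- vapply(seq_len(reps), function(r) {
    co <- simulate_cohort(
      groups = tibble::tibble(
        label = c("lo", "hi"), n_participants = 10L, perturbation = 0,
        coupling_strength = c(1.2, 1.6)
      ),
      t_len = 150L, sampler = "metropolis", seed = 9000 + r
    )
    ling <- lapply(c("lo", "hi"), function(g) {
      ids <- co$metadata$participant_id[co$metadata$group == g]
      ls <- energy_landscape(co$models[[g]])
      st <- dplyr::filter(co$states, participant_id %in% ids)
      transition_and_staying_rates(st, ls)$lingering
    })
    stats::t.test(ling[[2]], ling[[1]], alternative = "greater")$p.value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.5)
})
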