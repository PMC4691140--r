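test_that("backbone-adjacent contacts are never rupture candidates", {
  # 3-site chain folded so all three pairs touch: only (1,3) is breakable
  st <- new_cg_structure(data.frame(
    chain = "A", resno = 1:3, insert = "", resid = "ALA",
    x = c(0, 3.8, 5.0), y = c(0, 0, 3.0), z = 0, bfactor = NA_real_))
  topo <- build_kirchhoff(st)
  expect_equal(nrow(topo$contacts), 3L)
  expect_equal(breakable_pairs(topo, st), cbind(1L, 3L))

  # adjacent residue numbers on different chains are not bonded
  st2 <- new_cg_structure(data.frame(
    chain = c("A", "B"), resno = c(1L, 2L), insert = "", resid = "ALA",
    x = c(0, 4), y = 0, z = 0, bfactor = NA_real_))
  topo2 <- build_kirchhoff(st2)
  expect_equal(breakable_pairs(topo2, st2), cbind(1L, 2L))

  # a bare chain has nothing to break: unfolding terminates at step 0
  ch <- make_linear_chain(10)
  topo3 <- build_kirchhoff(ch)
  expect_equal(nrow(breakable_pairs(topo3, ch)), 0L)
  traj <- unfold(ch, topo3, snapshot_lnnc = integer(0))
  expect_equal(nrow(traj$events), 0L)
})

test_that("unfolding is deterministic and conserves contacts", {
  td <- make_two_domain_network(12L, 0.7, seed = 21)
  t1 <- unfold(td$structure, snapshot_lnnc = c(5L, 10L))
  t2 <- unfold(td$structure, snapshot_lnnc = c(5L, 10L))
  expect_identical(t1$events, t2$events)

  n0 <- nrow(t1$initial_topology$contacts)
  brk <- breakable_pairs(t1$initial_topology, td$structure)
  expect_equal(nrow(t1$events), nrow(brk))
  expect_equal(t1$events$lnnc, t1$events$step)
  # conservation at the snapshots: remaining + lnnc = initial
  for (nm in names(t1$snapshots)) {
    lnnc <- as.integer(sub("lnnc_", "", nm))
    expect_equal(nrow(t1$snapshots[[nm]]$contacts) + lnnc, n0)
  }
})

test_that("replaying the greedy rule confirms every rupture was maximal", {
  td <- make_two_domain_network(14L, 0.6, seed = 8)
  st <- td$structure
  topo <- build_kirchhoff(st)
  expect_lte(topo$n_sites, 50L)
  traj <- unfold(st, topo, snapshot_lnnc = integer(0))
  brk0 <- breakable_pairs(topo, st)
  key <- function(p) p[, 1] * 1000L + p[, 2]
  cur <- topo
  for (k in seq_len(nrow(traj$events))) {
    ev <- traj$events[k, ]
    live_brk <- cur$contacts[key(cur$contacts) %in% key(brk0), ,
                             drop = FALSE]
    m <- gnmunfold:::msfid_for_pairs(decompose(cur), live_brk)
    picked <- which(live_brk[, 1] == ev$i & live_brk[, 2] == ev$j)
    expect_length(picked, 1L)
    expect_gte(m[picked], max(m) * (1 - 1e-9))
    expect_equal(ev$msfid, m[picked], tolerance = 1e-10)
    keep <- key(cur$contacts) != key(cbind(ev$i, ev$j))
    cur <- kirchhoff_from_contacts(cur$n_sites,
                                   cur$contacts[keep, , drop = FALSE])
  }
  expect_equal(nrow(cur$contacts),
               nrow(topo$contacts) - nrow(traj$events))
})

test_that("reduced temperatures start at 1, monotonize by running maximum", {
  expect_equal(reduced_temperatures(c(5, 4, 2))$raw, c(1, 1.25, 2.5))
  # monotone case: raw and reported coincide
  expect_equal(reduced_temperatures(c(5, 4, 2))$reported, c(1, 1.25, 2.5))
  # softening case: a rupture raises the next maximal MSFID
  tt <- reduced_temperatures(c(4, 5, 2))
  expect_equal(tt$raw, c(1, 0.8, 2))
  expect_equal(tt$reported, c(1, 1, 2))
  expect_error(reduced_temperatures(c(4, 0, 1)), "step 2")
  expect_error(reduced_temperatures(c(4, Inf)), "step 2")
})

test_that("overlapping shortcuts produce a cooperative cascade at one temperature", {
  # 6-site chain with long-range contacts (1,6) and (2,5); (3,4) duplicates
  # a backbone pair. Series-parallel resistance gives MSFID(1,6) =
  # 3 * (1 || 1 + 3/4 + 1) = 2.2 and, once (1,6) is gone,
  # MSFID(2,5) = 3 * (1 || 3) = 2.25 > 2.2 -- so the second rupture
  # happens below the running maximum: a two-event jump.
  ch6 <- make_linear_chain(6)
  topo <- kirchhoff_from_contacts(6L, rbind(cbind(1:5, 2:6),
                                            c(1, 6), c(2, 5), c(3, 4)))
  traj <- unfold(ch6, topo, snapshot_lnnc = integer(0))
  expect_equal(traj$events$msfid, c(2.2, 2.25), tolerance = 1e-12)
  expect_equal(traj$events$t_raw, c(1, 2.2 / 2.25), tolerance = 1e-12)
  expect_equal(traj$events$t_over_t0, c(1, 1))
  jumps <- detect_jumps(traj, min_jump_size = 2L)
  expect_equal(nrow(jumps), 1L)
  expect_equal(jumps$size, 2L)
  expect_equal(jumps$t_over_t0, 1)
})

test_that("disjoint shortcuts of shrinking span stiffen strictly: no jumps", {
  # shortcut spanning k backbone steps has effective resistance k/(k+1):
  # spans 5, 4, 3, 2 give MSFID 2.5, 2.4, 2.25, 2.0, non-interacting
  ch <- make_linear_chain(30)
  topo <- kirchhoff_from_contacts(
    30L, rbind(cbind(1:29, 2:30),
               c(2, 7), c(10, 14), c(17, 20), c(23, 25)))
  traj <- unfold(ch, topo, snapshot_lnnc = integer(0))
  expect_equal(traj$events$msfid, c(2.5, 2.4, 2.25, 2.0),
               tolerance = 1e-12)
  expect_true(all(diff(traj$events$t_raw) > 0))
  expect_identical(traj$events$t_raw, traj$events$t_over_t0)
  expect_equal(nrow(detect_jumps(traj, min_jump_size = 2L)), 0L)
})

test_that("jump detection groups runs of constant reported temperature", {
  fake <- structure(list(events = data.frame(
    step = 1:40, t_over_t0 = c(rep(1, 30), seq(1.1, 2, length.out = 10)))),
    class = "unfolding_trajectory")
  j <- detect_jumps(fake, min_jump_size = 10L)
  expect_equal(nrow(j), 1L)
  expect_equal(j$size, 30L)
  expect_equal(j$lnnc_before, 0L)
  expect_equal(j$lnnc_after, 30L)

  rising <- structure(list(events = data.frame(
    step = 1:10, t_over_t0 = seq(1, 2, length.out = 10))),
    class = "unfolding_trajectory")
  expect_equal(nrow(detect_jumps(rising, min_jump_size = 2L)), 0L)
})

test_that("reported temperature is non-decreasing on every trajectory", {
  for (seed in 1:5) {
    td <- make_two_domain_network(10L, 0.8, seed = seed)
    traj <- unfold(td$structure, snapshot_lnnc = integer(0))
    expect_true(all(diff(traj$events$t_over_t0) >= 0))
    expect_equal(traj$events$t_over_t0[1], 1.0)
  }
})

test_that("melting summary converts jump temperatures and orders domains", {
  td <- make_two_domain_network(16L, 0.5, seed = 5)
  traj <- unfold(td$structure, snapshot_lnnc = integer(0))
  ann_idx <- resolve_annotation(td$annotation, td$structure)
  ms <- melting_summary(traj, ann_idx, T0_kelvin = 300,
                        min_jump_size = 5L)
  expect_equal(ms$unfolding_order, c("A", "B"))
  a <- ms$domains[ms$domains$label == "A", ]
  b <- ms$domains[ms$domains$label == "B", ]
  expect_lt(a$median_step, b$median_step)
  expect_lte(a$melt_kelvin, b$melt_kelvin)
  expect_equal(ms$domains$melt_kelvin,
               300 * ms$domains$jump_t_over_t0)

  # a domain with no internal breakable contacts is excluded with warning
  ann2 <- c(ann_idx, list(linker = td$truth$idx_linker[1:2]))
  expect_warning(melting_summary(traj, ann2, min_jump_size = 5L),
                 "linker")
})

test_that("snapshots beyond the final LNNC are omitted with a warning", {
  td <- make_two_domain_network(8L, 0.9, seed = 2)
  expect_warning(
    traj <- unfold(td$structure, snapshot_lnnc = c(5L, 99999L)),
    "omitted")
  expect_named(traj$snapshots, "lnnc_5")
})

test_that("trajectory tables serialize with temperature annotations", {
  td <- make_two_domain_network(8L, 0.9, seed = 2)
  traj <- unfold(td$structure, snapshot_lnnc = integer(0))
  f <- tempfile(fileext = ".tsv")
  write_trajectory(traj, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), nrow(traj$events))
  expect_true(all(c("step", "msfid", "lnnc", "T_over_T0") %in%
                    names(tab)))
})
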