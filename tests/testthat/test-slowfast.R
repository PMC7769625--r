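# manifold over the fold region of the bursting configuration; coarse but
# fine enough to resolve both folds
manifold_fixture <- function() fixture("manifold", {
  compute_critical_manifold(bursting_params(),
                            hA_grid = seq(0, 0.15, length.out = 61),
                            Ca_grid = seq(0.05, 0.6, length.out = 23),
                            n_V = 301)
})

test_that("critical manifold has the fold structure of a Z-shaped surface", {
  man <- manifold_fixture()
  expect_true(all(man$sheet$n_roots %in% c(1L, 3L)))
  tri <- man$sheet[man$sheet$n_roots == 3, ]
  expect_gt(nrow(tri), 0)
  # lower sheet stable, middle sheet saddle wherever three roots coexist
  expect_true(all(tri$stable[tri$sheet == "lower"]))
  expect_true(all(!tri$stable[tri$sheet == "middle"]))
  # middle-sheet saddles have a single real unstable eigenvalue
  expect_true(all(tri$max_re[tri$sheet == "middle"] > 0))
  # both folds found over the calcium range where the band exists
  expect_gt(sum(man$folds$curve == "SN1"), 3)
  expect_gt(sum(man$folds$curve == "SN2"), 3)
})

test_that("manifold slices agree with fast-subsystem continuation", {
  man <- manifold_fixture()
  Ca0 <- man$sheet$Ca[which.min(abs(unique(man$sheet$Ca) - 0.25))]
  slice <- man$sheet[abs(man$sheet$Ca - Ca0) < 1e-9, ]
  br <- continue_equilibria(bursting_params(), "hA", c(0, 0.15), fast = TRUE,
                            Ca = Ca0, start_V = -25, h0 = 5e-3)
  for (i in seq(1, nrow(slice), by = 7)) {
    dV <- abs(br$V - slice$V[i]) + 50 * abs(br$par - slice$hA[i])
    j <- which.min(dV)
    # the slice point lies on the continued branch
    Vb <- approx(br$par[c(j - 1, j, j + 1)][!is.na(br$par[c(j - 1, j, j + 1)])],
                 br$V[c(j - 1, j, j + 1)][!is.na(br$V[c(j - 1, j, j + 1)])],
                 xout = slice$hA[i], rule = 2)$y
    expect_lt(abs(Vb - slice$V[i]), 1e-3)
  }
})

test_that("SN and HB loci run nearly parallel across calcium", {
  man <- manifold_fixture()
  sn2 <- man$folds[man$folds$curve == "SN2", ]
  hb <- man$hopf
  shared <- intersect(round(sn2$Ca, 6), round(hb$Ca, 6))
  expect_gt(length(shared), 4)
  gap <- vapply(shared, function(ca) {
    sn2$hA[round(sn2$Ca, 6) == ca][1] - hb$hA[round(hb$Ca, 6) == ca][1]
  }, 1)
  expect_true(all(gap > 0))          # HB sits below the upper fold in hA
  expect_lt(sd(gap) / mean(gap), 0.8) # near-constant offset: parallel copies
})

test_that("burst overlay: onset at the SN1 fold, calcium rises when active", {
  man <- manifold_fixture()
  ov <- overlay_burst(bursting_traj(), man)
  expect_gte(nrow(ov$crossings), 3)
  # burst onsets happen at the lower fold: hA at onset matches the SN1
  # curve at the trajectory's calcium within one manifold grid cell
  cell <- diff(range(man$sheet$hA)) / 60
  expect_lt(median(abs(ov$crossings$d_SN1)), 2 * cell)
  # slow-variable kinetics of fold-initiated bursting
  expect_gt(ov$stats$mean_dCa_active, 0)
  expect_lt(ov$stats$mean_dCa_silent, 0)
  # the silent phase tracks the lower stable sheet
  expect_gt(ov$stats$frac_silent_near_lower_sheet, 0.9)
  # labels alternate in contiguous runs and every spike is in an active run
  runs <- rle(ov$samples$phase)
  expect_true(all(runs$values[-1] != head(runs$values, -1)))
  sp <- detect_spikes(ov$samples)
  ph_at_spike <- ov$samples$phase[findInterval(sp, ov$samples$t)]
  expect_true(all(ph_at_spike == "active"))
})

test_that("overlay refuses a non-bursting trajectory", {
  man <- manifold_fixture()
  expect_error(overlay_burst(tonic_post(), man), "not bursting")
})

test_that("slow-plane bifurcation curves assemble from equilibrium scans", {
  curves <- bifurcation_set_2d(bursting_params(),
                               Ca_grid = seq(0.1, 0.5, by = 0.05),
                               hA_range = c(0, 0.15))
  expect_true(all(c("SN1", "SN2", "HB") %in% curves$curve))
  # each equilibrium-based curve spans the calcium grid continuously
  for (cv in c("SN1", "SN2")) {
    cc <- curves[curves$curve == cv, ]
    expect_gte(nrow(cc), 4)
    expect_true(!is.unsorted(cc$Ca))
  }
})
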