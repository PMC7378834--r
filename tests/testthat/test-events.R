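test_that("trace extraction averages ROI pixels", {
  om <- oracle_movie(seed = 7)
  terrs <- om$sim$territories

  ## uniform frames give constant traces
  d <- dim(om$sim$movie$activity)
  mov7 <- imaging_movie(om$sim$movie$structural,
                        array(7, d), om$config$frame_interval,
                        om$config$pixel_size)
  tr7 <- extract_traces(mov7, terrs)
  expect_true(all(vapply(tr7, function(t) all(t$f == 7), logical(1))))

  ## a single-pixel ROI reproduces that pixel's series
  one_px <- terrs[1]
  one_px[[1]]$microdomains <- list(list(gi = 0, gj = 0,
                                        pixels = terrs[[1]]$soma_mask[1]))
  one_px[[1]]$arborization_mask <- terrs[[1]]$soma_mask[2]
  tr1 <- extract_traces(om$sim$movie, structure(one_px, class = "territory_set"))
  act <- matrix(om$sim$movie$activity, d[1] * d[2], d[3])
  md_tr <- Find(function(t) t$compartment == "microdomain", tr1)
  expect_equal(md_tr$f, act[terrs[[1]]$soma_mask[1], ])

  ## an injected transient confined to one microdomain moves only that trace
  ev <- om$sim$events
  md_ev <- ev[ev$compartment == "microdomain", ][1, ]
  tr <- extract_traces(om$sim$movie, terrs)
  for (t in tr) {
    if (t$compartment != "microdomain" || t$cell_id != md_ev$cell_id) next
    dev <- diff(range(t$f))
    if (t$roi_id == md_ev$roi_id) expect_gt(dev, 1)
    else {
      other <- ev[ev$roi_id == t$roi_id, ]
      if (!nrow(other)) expect_lt(dev / mean(t$f), 1e-9)
    }
  }
})

test_that("delta-F/F is the paper's normalization", {
  tr <- bare_trace(rep(10, 60))
  expect_equal(compute_dff(tr, c(0, 10))$dff, rep(0, 60))
  tr2 <- bare_trace(c(rep(10, 30), rep(20, 30)))
  expect_equal(compute_dff(tr2, c(0, 10))$dff[31:60], rep(1, 30))
  tr3 <- bare_trace(c(rep(10, 30), rep(13, 30)))
  expect_equal(max(compute_dff(tr3, c(0, 10))$dff), 0.3)
  expect_error(compute_dff(bare_trace(rep(0, 40)), c(0, 10)), "positive")
})

test_that("the 3-SD rule separates supra- from sub-threshold bumps", {
  set.seed(71)
  dt <- 0.5
  n_base <- 2000
  base_f <- 100 * (1 + 0.02 * rnorm(n_base)) # 2% dff noise in baseline
  bump <- function(peak_sd) {
    sdd <- sd((base_f - 100) / 100)
    100 * (1 + peak_sd * sdd * c(0.2, 0.9, 1, 0.9, 0.2))
  }
  cfgev <- event_config(baseline_window = c(0, n_base * dt))
  tr_hi <- bare_trace(c(base_f, bump(3.5), rep(100, 10)), dt)
  tr_lo <- bare_trace(c(base_f, bump(2.9), rep(100, 10)), dt)
  expect_equal(nrow(detect_events(tr_hi, cfgev)), 1)
  expect_equal(nrow(detect_events(tr_lo, cfgev)), 0)

  ## onset <= peak_time and amplitude above threshold
  ev <- detect_events(tr_hi, cfgev)
  expect_lte(ev$onset, ev$peak_time)
  expect_gt(ev$amplitude + attr(ev, "baseline_mean"), attr(ev, "threshold"))
})

test_that("per-frame false positives on pure noise match the normal tail", {
  set.seed(72)
  dt <- 0.5
  supra <- 0; frames <- 0
  cfgev <- event_config(baseline_window = c(0, 1000), min_separation = 0)
  for (i in 1:100) {
    f <- 100 * (1 + 0.05 * rnorm(3000))
    ev <- detect_events(bare_trace(f, dt), cfgev)
    ## count only analysis frames (beyond the baseline window)
    thr <- attr(ev, "threshold")
    dff <- (f - mean(f[1:2000])) / mean(f[1:2000])
    supra <- supra + sum(dff[2001:3000] > thr)
    frames <- frames + 1000
  }
  p0 <- pnorm(3, lower.tail = FALSE) # 0.00135
  ci <- qnorm(c(0.005, 0.995)) * sqrt(frames * p0 * (1 - p0)) + frames * p0
  expect_gte(frames, 1e5)
  expect_gte(supra, ci[1])
  expect_lte(supra, ci[2])
})

test_that("event detection is monotone in k_sd and scale-invariant", {
  set.seed(73)
  f <- 100 * (1 + 0.03 * rnorm(200))
  f[120:130] <- f[120:130] + 15
  f[160:170] <- f[160:170] + 8
  tr <- bare_trace(f, 0.5)
  counts <- vapply(c(1, 2, 3, 5, 8), function(k) {
    nrow(detect_events(tr, event_config(k_sd = k, baseline_window = c(0, 50))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  ## multiplying f by a positive constant changes nothing
  cfgev <- event_config(baseline_window = c(0, 50))
  e1 <- detect_events(tr, cfgev)
  e2 <- detect_events(bare_trace(13.7 * f, 0.5), cfgev)
  expect_equal(e1$onset, e2$onset)
  expect_equal(e1$amplitude, e2$amplitude, tolerance = 1e-12)
})

test_that("responder classification follows the grace-window rule", {
  pr <- stimulus_protocol(30, 20, 2, 2)
  cfgev <- event_config()
  mk_ev <- function(peak) {
    structure(data.frame(roi_id = "r", compartment = "soma", onset = peak - 1,
                         peak_time = peak, offset = peak + 1, amplitude = 1,
                         n_frames = 5),
              class = c("calcium_events", "data.frame"))
  }
  expect_true(classify_responder(mk_ev(35), pr, cfgev))    # during stimulus
  expect_false(classify_responder(mk_ev(0.5), pr, cfgev))  # long before onset
  expect_true(classify_responder(mk_ev(59), pr, cfgev))    # offset + 9 s
  expect_false(classify_responder(mk_ev(61), pr, cfgev))   # past the grace
})

test_that("population response spans 0 to 100% and requires QC-passing cells", {
  om <- oracle_movie(seed = 5)
  terrs <- om$sim$territories
  d <- dim(om$sim$movie$activity)

  ## all-responders movie: add a huge global transient
  act <- om$sim$movie$activity
  act[, , 50:70] <- act[, , 50:70] * 3
  mov_all <- imaging_movie(om$sim$movie$structural, act, 0.5,
                           om$config$pixel_size)
  pop_all <- population_response(terrs, extract_traces(mov_all, terrs),
                                 om$protocol, event_config())
  expect_equal(pop_all$soma, 100)
  expect_equal(pop_all$microdomain, 100)

  ## flat movie: no responders anywhere
  mov_none <- imaging_movie(om$sim$movie$structural, array(50, d), 0.5,
                            om$config$pixel_size)
  pop_none <- population_response(terrs, extract_traces(mov_none, terrs),
                                  om$protocol, event_config())
  expect_equal(pop_none$microdomain, 0)

  ## zero QC-passing territories is an error
  bad <- lapply(terrs, function(t) { t$qc$edge_clipped <- TRUE; t })
  expect_error(population_response(structure(bad, class = "territory_set"),
                                   extract_traces(mov_none, terrs),
                                   om$protocol, event_config()),
               "QC")
})

test_that("event rates convert counts to per-minute", {
  ev <- structure(data.frame(peak_time = c(10, 30)),
                  class = c("calcium_events", "data.frame"))
  expect_equal(event_rate(ev, c(0, 60)), 2)
  expect_equal(event_rate(structure(data.frame(peak_time = numeric(0)),
                                    class = c("calcium_events", "data.frame")),
                          c(0, 60)), 0)
  ev3 <- structure(data.frame(peak_time = c(21, 25, 30)),
                   class = c("calcium_events", "data.frame"))
  expect_equal(event_rate(ev3, c(20, 40)), 9)
  expect_error(event_rate(ev, c(10, 10)), "window")
})

test_that("reliability histograms match the binomial law", {
  m <- matrix(FALSE, 10, 5)
  m[1, ] <- TRUE
  rel <- reliability(m)
  expect_equal(unname(rel[["5"]]), 1)
  expect_equal(unname(rel[["0"]]), 9)

  expect_equal(unname(reliability(matrix(FALSE, 4, 5))[["0"]]), 4)

  ## i.i.d. response probability 0.5 over 5 trains: Binomial(5, 0.5)
  set.seed(75)
  big <- matrix(runif(600 * 5) < 0.5, 600, 5)
  counts <- reliability(big)
  p_exp <- dbinom(0:5, 5, 0.5)
  gof <- suppressWarnings(chisq.test(as.numeric(counts), p = p_exp))
  expect_gt(gof$p.value, 0.001)

  expect_error(reliability(matrix(TRUE, 3, 1)), "2 trains")
  mna <- matrix(TRUE, 3, 3); mna[2, 3] <- NA
  expect_error(reliability(mna), "ragged")
})
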