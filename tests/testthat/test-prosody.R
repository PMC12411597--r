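test_that("f0 preprocessing interpolates unvoiced frames and holds edges", {
  track <- tibble::tibble(time_s = c(0, 1, 2),
                          f0_hz = c(200, 0, 300),
                          voiced = c(TRUE, FALSE, TRUE))
  # filter needs 5 voiced frames; check interpolation alone first
  expect_error(preprocess_f0(track), "voiced frames")
  track5 <- tibble::tibble(
    time_s = 0:6, f0_hz = c(200, 0, 300, 250, 240, 230, 220),
    voiced = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  pp <- preprocess_f0(track5, smooth = FALSE)
  expect_equal(pp$f0_hz[2], 250)  # linear midpoint between 200 and 300
  edge <- tibble::tibble(
    time_s = 0:6, f0_hz = c(0, 210, 220, 230, 240, 250, 0),
    voiced = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  ppe <- preprocess_f0(edge, smooth = FALSE)
  expect_equal(ppe$f0_hz[c(1, 7)], c(210, 250))  # nearest voiced value
  expect_equal(ppe$time_s, edge$time_s)
  expect_equal(ppe$voiced, edge$voiced)
})

test_that("Savitzky-Golay smoothing preserves constants and is exact on cubics", {
  const <- tibble::tibble(time_s = seq(0, 1, 0.05), f0_hz = 200,
                          voiced = TRUE)
  expect_equal(preprocess_f0(const)$f0_hz, const$f0_hz)
  t <- seq(0, 1, length.out = 41)
  cubic <- 200 + 30 * t - 50 * t^2 + 20 * t^3
  track <- tibble::tibble(time_s = t, f0_hz = cubic, voiced = TRUE)
  sm <- preprocess_f0(track)$f0_hz
  interior <- 3:39  # edges use asymmetric fits
  expect_equal(sm[interior], cubic[interior], tolerance = 1e-9)
})

test_that("semitone variability matches the two-frame closed form and scale invariance", {
  two <- tibble::tibble(time_s = c(0, 1), f0_hz = c(200, 400),
                        voiced = TRUE)
  expect_equal(f0_variability_semitones(two), 12 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(f0_variability_semitones(two), 8.485, tolerance = 1e-3)
  const <- tibble::tibble(time_s = 0:5, f0_hz = 200, voiced = TRUE)
  expect_equal(f0_variability_semitones(const), 0)
  expect_error(f0_variability_semitones(const[1, ]), "2 frames")
})

test_that("first-accent F0 finds a constructed peak and scales homogeneously", {
  fx <- sample_prosody_fixture(contour = "peak", f0_base = 200,
                               f0_peak = 310)
  pp <- preprocess_f0(fx$pitch, smooth = FALSE)
  expect_equal(first_accent_f0(pp, fx$alignment), 310)
  fx2 <- sample_prosody_fixture(contour = "peak", f0_base = 400,
                                f0_peak = 620)
  pp2 <- preprocess_f0(fx2$pitch, smooth = FALSE)
  expect_equal(first_accent_f0(pp2, fx2$alignment),
               2 * first_accent_f0(pp, fx$alignment))
  # midpoint alternative stays inside the word
  expect_lte(first_accent_f0(pp, fx$alignment, method = "midpoint"), 310)
})

test_that("tempo is vowels per second and inversely homogeneous under time stretch", {
  al <- tibble::tibble(
    tier = "phones",
    label = c("K", "AA1", "K", "IY0", "K", "UW1", "EH0", "OW1"),
    start = seq(0, by = 0.25, length.out = 8),
    end = seq(0.25, by = 0.25, length.out = 8))
  expect_equal(speech_tempo(al), 5 / 2.0)  # 5 vowels over 2 s
  stretched <- dplyr::mutate(al, start = start * 2, end = end * 2)
  expect_equal(speech_tempo(stretched), speech_tempo(al) / 2)
  no_vowel <- dplyr::filter(al, !is_vowel_label(label))
  expect_equal(speech_tempo(no_vowel), 0)
})

test_that("vowel duration z-scores standardize within cells and resist scaling", {
  toks <- tibble::tibble(label = "AA1", duration = c(0.1, 0.3))
  z <- vowel_duration_z(toks)$z
  expect_equal(z, c(-1, 1) / sqrt(2), tolerance = 1e-6)
  set.seed(2)
  many <- tibble::tibble(label = rep(c("AA1", "IY0"), each = 20),
                         duration = runif(40, 0.05, 0.3))
  z1 <- vowel_duration_z(many)
  for (lab in c("AA1", "IY0")) {
    zz <- z1$z[z1$label == lab]
    expect_equal(mean(zz), 0, tolerance = 1e-9)
    expect_equal(sd(zz), 1, tolerance = 1e-9)
  }
  z2 <- vowel_duration_z(dplyr::mutate(many, duration = duration * 2))
  expect_equal(z2$z, z1$z)
  expect_warning(vowel_duration_z(
    tibble::tibble(label = c("AA1", "IY0"), duration = c(0.1, 0.2))),
    "degenerate")
})

test_that("all four measures equal fixture ground truth with smoothing disabled", {
  for (ct in c("constant", "rise", "peak")) {
    fx <- sample_prosody_fixture(n_words = 4, contour = ct, seed = 7)
    got <- prosody_measures(fx$pitch, fx$alignment, smooth = FALSE)
    expect_equal(as.numeric(got), as.numeric(fx$true_measures),
                 tolerance = 1e-6)
  }
  # constant contour: exactly zero variability
  fx0 <- sample_prosody_fixture(contour = "constant")
  expect_equal(fx0$true_measures$f0_sd_semitones, 0)
  expect_error(sample_prosody_fixture(vowel_duration = -0.1), "positive")
})

test_that("semitone scale-invariance and tempo time-scaling hold on random fixtures", {
  for (s in 1:100) {
    fx <- sample_prosody_fixture(
      n_words = 2 + s %% 3, contour = "rise",
      f0_base = 150 + s, f0_end = 250 + 2 * s,
      jitter_sd = 0.1, seed = s)
    m <- prosody_measures(fx$pitch, fx$alignment, smooth = FALSE)
    k <- 1.5
    scaled <- fx$pitch
    scaled$f0_hz <- scaled$f0_hz * k
    ms <- prosody_measures(scaled, fx$alignment, smooth = FALSE)
    expect_equal(ms$f0_sd_semitones, m$f0_sd_semitones, tolerance = 1e-9)
    expect_equal(ms$first_accent_f0_hz, k * m$first_accent_f0_hz)
    al2 <- dplyr::mutate(fx$alignment, start = start * 2, end = end * 2)
    expect_equal(speech_tempo(al2), speech_tempo(fx$alignment) / 2)
  }
})

test_that("fixtures with unvoiced consonants recover the linear contour by interpolation", {
  fx <- sample_prosody_fixture(contour = "rise", f0_base = 200,
                               f0_end = 300, unvoiced_consonants = TRUE)
  pp <- preprocess_f0(fx$pitch, smooth = FALSE)
  # interior unvoiced frames sit on the analytic line
  interior <- !fx$pitch$voiced &
    fx$pitch$time_s > min(fx$pitch$time_s[fx$pitch$voiced]) &
    fx$pitch$time_s < max(fx$pitch$time_s[fx$pitch$voiced])
  expect_equal(pp$f0_hz[interior], fx$f0_fun(fx$pitch$time_s[interior]),
               tolerance = 1e-9)
})

test_that("TextGrid and pitch CSV round-trip a fixture", {
  fx <- sample_prosody_fixture(n_words = 3, contour = "peak")
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_prosody_fixture(fx, tg, pc)
  al <- read_textgrid(tg)
  expect_equal(al$label, fx$alignment$label)
  expect_equal(al$start, fx$alignment$start, tolerance = 1e-9)
  expect_equal(al$end, fx$alignment$end, tolerance = 1e-9)
  tr <- read_pitch(pc)
  expect_equal(tr$f0_hz, fx$pitch$f0_hz, tolerance = 1e-9)
  expect_equal(tr$voiced, fx$pitch$voiced)
  # measures computed from the files match the in-memory fixture
  got <- prosody_measures(tr, al, smooth = FALSE)
  expect_equal(as.numeric(got), as.numeric(fx$true_measures),
               tolerance = 1e-6)
})

test_that("prosody report detects a constructed +2 semitone shift and handles identity", {
  set.seed(5)
  base <- tibble::tibble(
    condition = "a",
    first_accent_f0_hz = 200 * 2^(rnorm(30, 0, 0.3) / 12),
    f0_sd_semitones = abs(rnorm(30, 2, 0.3)),
    tempo_vowels_per_sec = rnorm(30, 4, 0.3),
    mean_vowel_duration_s = rnorm(30, 0.12, 0.01))
  shifted <- dplyr::mutate(base, condition = "b",
                           first_accent_f0_hz =
                             first_accent_f0_hz * 2^(2 / 12))
  rep <- prosody_report(dplyr::bind_rows(base, shifted))
  expect_equal(nrow(rep$summary), 8)  # 4 measures x 2 conditions
  pw <- rep$pairwise
  expect_equal(nrow(pw), 4)
  expect_lt(pw$p_value[pw$measure == "first_accent_f0_hz"], 0.01)
  one_sided <- suppressWarnings(wilcox.test(
    shifted$first_accent_f0_hz, base$first_accent_f0_hz,
    alternative = "greater", paired = TRUE, exact = FALSE))
  expect_lt(one_sided$p.value, 0.01)
  # identical paired samples: no evidence of difference
  same <- dplyr::bind_rows(base, dplyr::mutate(base, condition = "b"))
  rep2 <- prosody_report(same)
  expect_true(all(rep2$pairwise$p_value > 0.9))
  expect_warning(prosody_report(dplyr::bind_rows(
    base, tibble::tibble(condition = "c", first_accent_f0_hz = 1,
                         f0_sd_semitones = 1, tempo_vowels_per_sec = 1,
                         mean_vowel_duration_s = 0.1))),
    "skipping")
})
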