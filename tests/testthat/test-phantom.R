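test_that("empty phantom has empty gold and two-valued channels", {
  cfg <- tinyPhantomConfig(nLesions = 0L, confuserCount = 0L, noiseSd = 0,
                           misregOffset = c(0, 0, 0))
  st <- generateStudy(cfg)
  expect_equal(sum(volData(gold(st))), 0)
  # air outside the head, tissue inside, nothing else
  expect_setequal(unique(as.numeric(volData(t2w(st)))),
                  c(cfg@airLevel, cfg@backgroundLevel))
  expect_setequal(unique(as.numeric(volData(t1w(st)))),
                  c(cfg@airLevel, cfg@backgroundLevel))
})

test_that("gold voxels match a brute-force ellipsoid scan", {
  cfg <- tinyPhantomConfig(lesionRadiusRange = c(8, 8), noiseSd = 0,
                           t1HypoFraction = 0, confuserCount = 0L,
                           seed = 3L)
  st <- generateStudy(cfg)
  les <- attr(st, "lesions")[[1]]
  d <- dim(volData(gold(st)))
  sp <- spacing(gold(st))
  oracle <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    x <- (c(i, j, k) - 1) * sp
    oracle[i, j, k] <- sum(((x - les$cen) / les$rad)^2) <= 1
  }
  expect_equal(sum(volData(gold(st))), sum(oracle))
  expect_equal(volData(gold(st)) == 1, oracle)
})

test_that("identical seeds give bit-identical studies", {
  a <- generateStudy(tinyPhantomConfig(seed = 42L))
  b <- generateStudy(tinyPhantomConfig(seed = 42L))
  expect_identical(volData(t1w(a)), volData(t1w(b)))
  expect_identical(volData(t2w(a)), volData(t2w(b)))
  expect_identical(volData(gold(a)), volData(gold(b)))
  c <- generateStudy(tinyPhantomConfig(seed = 43L))
  expect_false(identical(volData(t2w(a)), volData(t2w(c))))
})

test_that("confusers never overlap gold and lesions are bright on ch2", {
  cfg <- tinyPhantomConfig(noiseSd = 0, confuserLevel = 0.7,
                           lesionLevelCh2 = 0.85, seed = 5L)
  st <- generateStudy(cfg)
  ch2 <- volData(t2w(st))
  g <- volData(gold(st)) == 1
  confuserVox <- ch2 == cfg@confuserLevel & !g
  expect_equal(sum(ch2[g] == cfg@confuserLevel), 0)
  expect_gt(sum(confuserVox), 0)
  expect_gt(mean(ch2[g]), mean(ch2[!g]))
})

test_that("zero offset and matched spacing align the two lesion supports", {
  cfg <- tinyPhantomConfig(misregOffset = c(0, 0, 0),
                           spacingCh1 = c(1, 1, 4), spacingCh2 = c(1, 1, 4),
                           t1HypoFraction = 0, noiseSd = 0)
  st <- generateStudy(cfg)
  ch1les <- volData(t1w(st)) == cfg@lesionLevelCh1
  expect_equal(ch1les, volData(gold(st)) == 1)
})

test_that("hypointense cut removes about the requested volume fraction", {
  cfg <- tinyPhantomConfig(spacingCh1 = c(0.5, 0.5, 1),
                           spacingCh2 = c(0.5, 0.5, 1),
                           gridShape = c(96L, 96L, 48L),
                           lesionRadiusRange = c(9, 11),
                           t1HypoFraction = 0.4, noiseSd = 0,
                           misregOffset = c(0, 0, 0), confuserCount = 0L)
  st <- generateStudy(cfg)
  lesionVox <- sum(volData(gold(st)))
  brightVox <- sum(volData(t1w(st)) == cfg@lesionLevelCh1)
  expect_equal(1 - brightVox / lesionVox, 0.4, tolerance = 0.08)
})

test_that("infeasible lesions fail naming the offending axis", {
  cfg <- tinyPhantomConfig(lesionRadiusRange = c(30, 40))
  expect_error(generateStudy(cfg), "axis")
})

test_that("cohort generation varies across patients and writes a manifest", {
  cfg <- tinyPhantomConfig(gridShape = c(32L, 32L, 6L),
                           lesionRadiusRange = c(4, 5),
                           confuserCount = 0L, misregOffset = c(0, 0, 0))
  cohort <- generateCohort(3, cfg, seed = 2L)
  expect_length(cohort, 3)
  expect_false(identical(volData(gold(cohort[[1]])),
                         volData(gold(cohort[[2]]))))
  dir <- withr::local_tempdir()
  writeCohort(cohort, dir, config = cfg)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$t2w)))
  rt <- readStudy(dir, man$patient_id[1])
  expect_equal(volData(gold(rt)), volData(gold(cohort[[1]])),
               tolerance = 1e-6)
  expect_equal(spacing(t2w(rt)), spacing(t2w(cohort[[1]])),
               tolerance = 1e-6)
})
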