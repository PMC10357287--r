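test_that("CSI and SFAR follow their defining arithmetic", {
  expect_equal(csi_score(0, 3, 6.8), 0)
  expect_equal(csi_score(110, 3.4, 6.8), 55, tolerance = 1e-12)
  expect_equal(csi_score(165, 5.6, 5.6), 165, tolerance = 1e-12)
  expect_error(csi_score(110, 3, 0), "mld")
  expect_equal(sfar(6.0, 6.0), 1.00)
  expect_equal(sfar(7.2, 6.0), 1.20)
  expect_error(sfar(-1, 6), "> 0")
  expect_gt(sfar(6.1, 5.6), 1)   # typical complication-prone combination
  expect_lt(sfar(5.85, 6.8), 1)  # typical uncomplicated combination
})

test_that("CSI is monotone in its arguments", {
  soa <- seq(50, 250, by = 25)
  expect_true(all(diff(csi_score(soa, 4, 6)) > 0))
  noc <- 1:8
  expect_true(all(diff(csi_score(120, noc, 6)) > 0))
  mld <- seq(4, 9, by = 0.5)
  expect_true(all(diff(csi_score(120, 4, mld)) < 0))
})

test_that("the two-step model classifies and attributes quadrants as published", {
  res <- classify_risk(data.frame(sfar = c(1.09, 0.86, 0.86),
                                  csi = c(55, 165, 55)))
  expect_equal(as.character(res$predicted),
               c("high_risk", "high_risk", "low_risk"))
  expect_equal(res$triggering_step, c("sfar_step", "csi_step", "none"))
  expect_equal(as.character(res$quadrant), c("QII", "QIV", "QI"))
})

test_that("both thresholds are strict: boundary values stay low risk", {
  res <- classify_risk(data.frame(sfar = c(1.00, 0.9, 1.0000001),
                                  csi = c(100, 100, 99)))
  expect_equal(as.character(res$predicted),
               c("low_risk", "low_risk", "high_risk"))
})

test_that("the quadrants partition the (SFAR, CSI) plane", {
  set.seed(5)
  pts <- data.frame(sfar = runif(500, 0.4, 1.6), csi = runif(500, 0, 300))
  q <- classify_risk(pts)$quadrant
  expect_false(anyNA(q))
  expect_equal(as.character(q),
               ifelse(pts$sfar > 1 & pts$csi > 100, "QIII",
                      ifelse(pts$sfar > 1, "QII",
                             ifelse(pts$csi > 100, "QIV", "QI"))))
})

test_that("classification ignores features outside the model's rules", {
  base <- data.frame(sfar = c(0.8, 1.2), csi = c(120, 40))
  with_noise <- cbind(base, mld = c(3, 9), age = c(70, 90))
  expect_equal(classify_risk(base)$predicted,
               classify_risk(with_noise)$predicted)
  expect_error(classify_risk(data.frame(csi = 50)), "missing feature")
})

test_that("a straight wide vessel assesses as low risk end to end", {
  a <- assess_patient(straight_vessel(205, 7), sheath_od = 6)
  expect_equal(a$csi, 0)
  expect_equal(a$sfar, 6 / 7, tolerance = 1e-12)
  expect_equal(a$predicted, "low_risk")
  expect_equal(a$quadrant, "QI")
  expect_equal(a$triggering_step, "none")
})

test_that("a tortuous narrow vessel triggers the CSI step", {
  ## five elbows of >= 30 degrees, MLD 5 mm, 5 mm sheath: SFAR = 1 (not > 1)
  ## and CSI = SOA * 5 / 5 = SOA > 100, so the CSI step must fire
  v <- elbow_vessel(c(30, 35, 40, 45, 50), rep(32, 6), diameter = 5)
  a <- assess_patient(v$cl, sheath_od = 5)
  expect_equal(a$profile$n_curves, 5L)
  expect_equal(a$sfar, 1, tolerance = 1e-12)
  expect_gt(a$csi, 100)
  expect_equal(a$predicted, "high_risk")
  expect_equal(a$triggering_step, "csi_step")
  expect_equal(a$quadrant, "QIV")

  ## widening the lumen to 12 mm leaves the decision to the CSI arithmetic
  wide <- centerline(v$cl$points, 12)
  aw <- assess_patient(wide, sheath_od = 5)
  soa <- aw$profile$sum_of_angles
  expect_equal(aw$csi, soa * 5 / 12, tolerance = 1e-9)
  expect_equal(aw$predicted,
               if (soa * 5 / 12 > 100) "high_risk" else "low_risk")
})

test_that("assessment picks up the worst plaque's calcification category", {
  v <- elbow_vessel(c(40), c(80, 80), diameter = 6)
  plq <- list(plaque(20, 35, "inner_wall", 0.3, 0.3, 0.5),
              plaque(100, 115, "outer_wall", 0.4, 0.7, 0.5))
  a <- assess_patient(v$cl, plq, sheath_od = 5.5)
  expect_equal(as.character(a$calc_category), "III")
  ## plaque narrowing reduces the measured MLD
  a0 <- assess_patient(v$cl, list(), sheath_od = 5.5)
  expect_lt(a$lumen$mld, a0$lumen$mld)
})

test_that("French size converts to a plausible outer diameter", {
  expect_equal(sheath_od_from_french(14), 14 / 3 + 0.8, tolerance = 1e-12)
  expect_error(sheath_od_from_french(-14), "french")
})

test_that("threshold models round-trip through JSON and predict consistently", {
  m <- ivc_default_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$rules, m$rules)
  nd <- data.frame(sfar = c(0.8, 1.3), csi = c(150, 20))
  expect_equal(predict(m, nd, type = "response"), c(1L, 1L))
  expect_equal(as.character(predict(m2, nd)), c("high_risk", "high_risk"))
})
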