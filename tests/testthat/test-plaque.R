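test_that("calcification categories follow the 50% boundaries", {
  expect_equal(as.character(calcification_category(0.30, 0.30)), "I")
  expect_equal(as.character(calcification_category(0.60, 0.40)), "II")
  expect_equal(as.character(calcification_category(0.40, 0.60)), "III")
  expect_equal(as.character(calcification_category(0.60, 0.60)), "IV")
  expect_equal(as.character(calcification_category(0.50, 0.50)), "IV")
  expect_error(calcification_category(1.2, 0.3), "\\[0, 1\\]")
  expect_error(calcification_category(0.3, -0.1), "\\[0, 1\\]")
})

test_that("categories partition the unit square exactly", {
  g <- seq(0, 1, by = 0.05)
  grid <- expand.grid(p = g, l = g)
  cats <- calcification_category(grid$p, grid$l)
  expect_false(anyNA(cats))
  ## each point lands in exactly one category and the category determines
  ## the indicator
  expect_equal(cag_high_risk(cats), grid$l >= 0.5)
  expect_equal(as.character(cats),
               ifelse(grid$p >= 0.5 & grid$l >= 0.5, "IV",
                      ifelse(grid$l >= 0.5, "III",
                             ifelse(grid$p >= 0.5, "II", "I"))))
})

test_that("plaque construction enforces its contract", {
  expect_error(plaque(20, 10, "inner_wall", 0.3, 0.3, 1), "span")
  expect_error(plaque(10, 20, "inner_wall", 1.3, 0.3, 1), "fraction")
  expect_error(plaque(10, 20, "circumferential", 0.3, 0.3, 1),
               "circumferential")
  expect_error(plaque(10, 20, "inner_wall", 0.3, 0.3, -1), "thickness")
  p <- plaque(10, 20, "outer_wall", 0.6, 0.6, 0.8)
  expect_equal(as.character(p$category), "IV")
})

test_that("free-lumen realignment is the identity without effective plaques", {
  v <- single_elbow(45)
  expect_identical(free_lumen_centerline(v$cl, list())$points, v$cl$points)
  circ <- plaque(v$peak_s - 10, v$peak_s + 10, "circumferential",
                 0.8, 0.4, 0.8)
  shifted <- free_lumen_centerline(v$cl, list(circ))
  expect_equal(shifted$points, v$cl$points, tolerance = 1e-12)
  ## but the lumen narrows inside the span
  s <- arc_length(v$cl)
  inside <- s >= circ$span[1] & s <= circ$span[2]
  expect_equal(shifted$sections$diameter[inside],
               v$cl$sections$diameter[inside] - 0.8)
  expect_equal(shifted$sections$diameter[!inside],
               v$cl$sections$diameter[!inside])
})

test_that("a circumferential plaque leaves the curve angle unchanged", {
  v <- single_elbow(45)
  cv <- detect_curves(v$cl)
  e <- poc_angle_effect(v$cl, list(plaque(v$peak_s - 10, v$peak_s + 10,
                                          "circumferential", 0.7, 0.4, 0.8)),
                        cv[1, ])
  expect_lt(abs(e$delta), 1e-6)
})

test_that("tip and bottom plaques move the angle in opposite directions", {
  v <- single_elbow(45, diameter = 6)
  cv <- detect_curves(v$cl)
  mk <- function(pos) plaque(v$peak_s - 10, v$peak_s + 10, pos, 0.3, 0.3, 0.9)
  inner <- poc_angle_effect(v$cl, list(mk("inner_wall")), cv[1, ])
  outer <- poc_angle_effect(v$cl, list(mk("outer_wall")), cv[1, ])
  expect_lt(inner$delta, 0)   # tip plaque straightens the lumen line
  expect_gt(outer$delta, 0)   # bottom plaque deepens the bend
  expect_lt(inner$delta * outer$delta, 0)
})

test_that("plaques up to 30% of the radius change the angle by at most ~10%", {
  for (ang in c(30, 45, 60)) {
    v <- single_elbow(ang, diameter = 6)
    cv <- detect_curves(v$cl)
    for (t in c(0.3, 0.6, 0.9)) {   # radius is 3 mm, so up to 30%
      for (pos in c("inner_wall", "outer_wall")) {
        e <- poc_angle_effect(v$cl, list(plaque(v$peak_s - 10, v$peak_s + 10,
                                                pos, 0.3, 0.3, t)), cv[1, ])
        expect_lte(abs(e$delta), 0.10 * cv$turn_angle[1])
      }
    }
  }
})

test_that("the same plaque perturbs a small vessel more than a large one", {
  d5 <- single_elbow(45, diameter = 5)
  d10 <- single_elbow(45, diameter = 10)
  delta_for <- function(v) {
    cv <- detect_curves(v$cl)
    poc_angle_effect(v$cl, list(plaque(v$peak_s - 10, v$peak_s + 10,
                                       "outer_wall", 0.3, 0.3, 1)),
                     cv[1, ])$delta
  }
  expect_gt(abs(delta_for(d5)), abs(delta_for(d10)))
})

test_that("the angle change grows with plaque thickness", {
  v <- single_elbow(45, diameter = 6)
  cv <- detect_curves(v$cl)
  deltas <- vapply(seq(0.1, 0.9, by = 0.2), function(t) {
    abs(poc_angle_effect(v$cl, list(plaque(v$peak_s - 10, v$peak_s + 10,
                                           "outer_wall", 0.3, 0.3, t)),
                         cv[1, ])$delta)
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("overlapping plaques on the same wall are rejected", {
  v <- single_elbow(45)
  a <- plaque(v$peak_s - 10, v$peak_s + 5, "inner_wall", 0.3, 0.3, 0.5)
  b <- plaque(v$peak_s - 2, v$peak_s + 10, "inner_wall", 0.3, 0.3, 0.5)
  expect_error(free_lumen_centerline(v$cl, list(a, b)), "overlapping")
  ## opposite walls may overlap
  b2 <- plaque(v$peak_s - 2, v$peak_s + 10, "outer_wall", 0.3, 0.3, 0.5)
  expect_s3_class(free_lumen_centerline(v$cl, list(a, b2)), "centerline")
})

test_that("plaque spans outside the vessel and oversized plaques are rejected", {
  v <- single_elbow(45)
  expect_error(free_lumen_centerline(
    v$cl, list(plaque(v$length - 5, v$length + 20, "inner_wall",
                      0.3, 0.3, 0.5))), "outside")
  expect_error(free_lumen_centerline(
    v$cl, list(plaque(v$peak_s - 5, v$peak_s + 5, "inner_wall",
                      0.3, 0.3, 3.5))), "radius")
})
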