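test_that("checklist and expert criteria resolve synonyms", {
  cl <- name_list(c("Cus dus", "Eus fus"),
                  synonyms = c("Aus bus" = "Cus dus"))
  expect_true(check_checklist("Cus dus", cl))
  expect_true(check_checklist("Aus bus", cl))   # synonym resolves
  expect_false(check_checklist("Gus hus", cl))
  empty <- name_list(character())
  expect_false(any(check_checklist(c("Cus dus", "Aus bus"), empty)))
  expect_true(check_expert("Aus bus", cl))      # shared resolution path
})

test_that("single-trap region is a geodesic disc", {
  trap <- c(lat = 51, lon = 10)
  region <- build_search_region(trap["lat"], trap["lon"], radius_km = 200)
  for (d in c(199, 201)) {
    pt_lat <- trap["lat"] + (d / R_EARTH) * 180 / pi  # due north
    expect_equal(hav_dist(trap["lat"], trap["lon"], pt_lat, trap["lon"]), d,
                 tolerance = 1e-6)
    expect_identical(unname(region_contains(region, pt_lat, trap["lon"])),
                     d < 200)
  }
  expect_true(region_contains(region, trap["lat"], trap["lon"]))  # trap itself
  expect_error(build_search_region(numeric(), numeric()), "zero traps")
})

test_that("degenerate hulls: two traps and collinear traps give stadiums", {
  lat <- c(50, 50, 50); lon <- c(8, 9, 10)  # collinear
  region <- build_search_region(lat, lon, radius_km = 100)
  expect_true(all(region_contains(region, lat, lon)))
  # midpoint offset perpendicular: ~80 km north of the segment is inside,
  # ~120 km is outside
  for (d in c(80, 120)) {
    plat <- 50 + (d / R_EARTH) * 180 / pi
    expect_identical(unname(region_contains(region, plat, 9)), d < 100)
  }
  two <- build_search_region(c(50, 50), c(8, 10), radius_km = 200)
  for (d in c(150, 250)) {
    plat <- 50 + (d / R_EARTH) * 180 / pi
    expect_identical(unname(region_contains(two, plat, 9)), d < 200)
  }
})

test_that("containment matches the haversine brute-force oracle", {
  set.seed(99)
  for (rep in 1:4) {
    k <- sample(3:6, 1)
    tlat <- runif(k, 48, 54); tlon <- runif(k, 7, 14)
    region <- build_search_region(tlat, tlon, radius_km = 200)
    qlat <- runif(60, 44, 58); qlon <- runif(60, 2, 19)
    got <- region_contains(region, qlat, qlon)
    for (i in seq_along(qlat)) {
      d <- oracle_hull_distance(qlat[i], qlon[i], tlat, tlon)
      if (abs(d - 200) < 0.5) next  # boundary band excluded
      expect_identical(unname(got[i]), d < 200,
                       label = sprintf("rep %d point %d (d = %.2f km)", rep, i, d))
    }
  }
})

test_that("every detection trap lies inside its own region; radius is monotone", {
  set.seed(5)
  tlat <- runif(5, 48, 54); tlon <- runif(5, 7, 14)
  r1 <- build_search_region(tlat, tlon, 50)
  expect_true(all(region_contains(r1, tlat, tlon)))
  qlat <- runif(200, 45, 57); qlon <- runif(200, 3, 18)
  inside_small <- region_contains(r1, qlat, qlon)
  inside_big <- region_contains(build_search_region(tlat, tlon, 300), qlat, qlon)
  expect_true(all(inside_big[inside_small]))  # enlarging never flips TRUE -> FALSE
})

test_that("occurrence check uses detection traps and record containment", {
  traps <- data.frame(trap_id = c("T1", "T2"),
                      latitude = c(50, 52), longitude = c(8, 11))
  det <- list("Aus bus" = c("T1", "T2"), "Cus dus" = "T1")
  occ <- data.frame(species = c("Aus bus", "Eus fus"),
                    latitude = c(50, 50), longitude = c(8, 8))
  res <- check_occurrences(c("Aus bus", "Cus dus"), det, traps, occ, 200)
  # record at a detection trap's exact coordinates -> TRUE
  expect_true(res$occurrence_ok[res$species == "Aus bus"])
  expect_identical(res$n_records_inside[res$species == "Aus bus"], 1L)
  # species absent from the db -> FALSE, not an error
  expect_false(res$occurrence_ok[res$species == "Cus dus"])
  # species with zero occupied traps skipped with a warning
  expect_warning(
    r2 <- check_occurrences("Gus hus", list("Gus hus" = character()),
                            traps, occ, 200),
    "zero occupied")
  expect_false(r2$occurrence_ok)
})

test_that("two-of-three consensus and permutation invariance", {
  expect_true(validate_species(TRUE, FALSE, TRUE))
  expect_false(validate_species(FALSE, FALSE, FALSE))
  expect_true(validate_species(TRUE, TRUE, TRUE))
  expect_false(validate_species(TRUE, FALSE, FALSE))
  # permutation invariance over all 8 boolean triples
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) for (c in c(TRUE, FALSE)) {
    v <- validate_species(a, b, c)
    expect_identical(v, validate_species(b, c, a))
    expect_identical(v, validate_species(c, a, b))
  }
  expect_true(validate_species(TRUE, FALSE, FALSE, min_criteria = 1))
  expect_error(validate_species(TRUE, NULL, NULL, min_criteria = 2),
               "min_criteria")
})

test_that("pairwise agreement matches direct counting", {
  res <- data.frame(expert_ok = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                    occurrence_ok = c(TRUE, FALSE, FALSE, TRUE, TRUE),
                    checklist_ok = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  m <- agreement_matrix(res)
  # hand count: expert vs occurrence agree on rows 1,3,5 -> 60%
  expect_equal(m["expert_ok", "occurrence_ok"], 60)
  expect_equal(m["expert_ok", "checklist_ok"], 80)
  expect_equal(m["occurrence_ok", "checklist_ok"], 40)
  expect_true(all(diag(m) == 100))
  # identical vectors -> 100, complementary -> 0
  m2 <- agreement_matrix(data.frame(a_ok = c(TRUE, FALSE),
                                    b_ok = c(TRUE, FALSE),
                                    c_ok = c(FALSE, TRUE)))
  expect_equal(m2["a_ok", "b_ok"], 100)
  expect_equal(m2["a_ok", "c_ok"], 0)
})
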