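test_that("ideal dimer is detected and the criterion edges are respected", {
  fr <- frame(0, ions = NULL, waters = hbond_dimer(r_oo = 2.9),
              box = box(50), wrap = FALSE)
  hb <- detect_hbonds(fr)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor, 1L)
  expect_equal(hb$acceptor, 2L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 0, tolerance = 1e-9)
  # distance just beyond the 3.5 A gate: rejected
  fr_far <- frame(0, ions = NULL, waters = hbond_dimer(r_oo = 3.51),
                  box = box(50), wrap = FALSE)
  expect_equal(nrow(detect_hbonds(fr_far)), 0L)
  fr_in <- frame(0, ions = NULL, waters = hbond_dimer(r_oo = 3.49),
                 box = box(50), wrap = FALSE)
  expect_equal(nrow(detect_hbonds(fr_in)), 1L)
  # angle just beyond the 30 degree gate: rejected
  fr_tilt <- frame(0, ions = NULL, waters = hbond_dimer(angle_deg = 30.5),
                   box = box(50), wrap = FALSE)
  expect_equal(nrow(detect_hbonds(fr_tilt)), 0L)
  fr_ok <- frame(0, ions = NULL, waters = hbond_dimer(angle_deg = 29.5),
                 box = box(50), wrap = FALSE)
  expect_equal(nrow(detect_hbonds(fr_ok)), 1L)
})

test_that("hydrogen bonds across the periodic boundary are detected", {
  w <- hbond_dimer(r_oo = 2.9, origin = c(9, 5, 5))  # acceptor at x = 11.9
  fr <- frame(0, ions = NULL, waters = w, box = box(10), wrap = TRUE)
  # after wrapping the pair is split across the boundary
  expect_lt(fr$waters$O[2, 1], fr$waters$O[1, 1])
  hb <- detect_hbonds(fr)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 0, tolerance = 1e-6)
})

test_that("detection matches a 27-image brute-force check on a dense box", {
  fr <- toy_water_box(25, box(9), seed = 11)
  hb <- detect_hbonds(fr)
  md <- water_model()
  L <- 9
  brute <- 0L
  for (don in 1:25) for (acc in 1:25) {
    if (don == acc) next
    doo <- brute_image_disp(fr$waters$O[don, ], fr$waters$O[acc, ], L)
    if (sqrt(sum(doo^2)) >= 3.5) next
    for (h in c("H1", "H2")) {
      oh <- fr$waters[[h]][don, ] - fr$waters$O[don, ]
      ang <- acos(min(1, max(-1, sum(oh * doo) /
                               sqrt(sum(oh^2) * sum(doo^2))))) * 180 / pi
      if (ang < 30) brute <- brute + 1L
    }
  }
  expect_equal(nrow(hb), brute)
  expect_gt(nrow(hb), 0L)   # the fixture actually exercises the criterion
})

# ring of n shell waters, each H-bonded to both neighbours
hbond_ring <- function(n = 6, r_ring = 2.9 / (2 * sin(pi / 6)), L = 40) {
  md <- water_model()
  ctr <- c(L / 2, L / 2, L / 2)
  O <- H1 <- H2 <- M <- matrix(0, n, 3)
  half <- md$theta_hoh / 2 * pi / 180
  for (i in 1:n) {
    a <- 2 * pi * (i - 1) / n
    o <- ctr + r_ring * c(cos(a), sin(a), 0)
    # one O-H pointing at the next oxygen in the ring
    nxt <- ctr + r_ring * c(cos(a + 2 * pi / n), sin(a + 2 * pi / n), 0)
    u <- (nxt - o) / sqrt(sum((nxt - o)^2))
    # second H out of plane to keep the rigid HOH angle
    perp <- c(0, 0, 1)
    v <- cos(md$theta_hoh * pi / 180) * u +
      sin(md$theta_hoh * pi / 180) * perp
    O[i, ] <- o
    H1[i, ] <- o + md$r_oh * u
    H2[i, ] <- o + md$r_oh * v
    bis <- (u + v) / sqrt(sum((u + v)^2))
    M[i, ] <- o + md$r_om * bis
  }
  water_set(O, H1, H2, M)
}

test_that("a closed ring gives exactly N_HW_HW = 2 per shell water", {
  n <- 6
  L <- 40
  w <- hbond_ring(n, L = L)
  fr <- frame(0, ions = sites(rep(L / 2, 3), 1, "ION"), waters = w,
              box = box(L), wrap = FALSE)
  r_ring <- 2.9 / (2 * sin(pi / 6))
  st <- shell_hbond_stats(trajectory(list(fr), dt = 1), shell = r_ring + 0.5)
  expect_equal(st$N_HW_HW, 2, tolerance = 1e-12)
  expect_equal(st$bridging_per_ion, 0)
})

test_that("a bridging water outside the shell is counted once per ion", {
  md <- water_model()
  L <- 40
  ctr <- c(L / 2, L / 2, L / 2)
  half <- md$theta_hoh / 2 * pi / 180
  # two shell waters on the x axis flanks, one bridge above between them
  mk_water <- function(o, u, perp = c(1, 0, 0)) {
    u <- u / sqrt(sum(u^2))
    perp <- perp - sum(perp * u) * u
    perp <- perp / sqrt(sum(perp^2))
    v <- cos(md$theta_hoh * pi / 180) * u + sin(md$theta_hoh * pi / 180) * perp
    bis <- (u + v) / sqrt(sum((u + v)^2))
    list(O = o, H1 = o + md$r_oh * u, H2 = o + md$r_oh * v,
         M = o + md$r_om * bis)
  }
  s1 <- ctr + c(-1.5, 0, 0)
  s2 <- ctr + c(1.5, 0, 0)
  bpos <- ctr + c(0, 2.6, 0)
  # bridge donates one H towards each shell water (geometric fixture; the
  # detector reads only O-H vectors, so the HOH angle may be unphysical)
  u1 <- (s1 - bpos); u2 <- (s2 - bpos)
  b <- list(O = bpos,
            H1 = bpos + md$r_oh * u1 / sqrt(sum(u1^2)),
            H2 = bpos + md$r_oh * u2 / sqrt(sum(u2^2)))
  b$M <- bpos + md$r_om * ((b$H1 - bpos) + (b$H2 - bpos)) /
    sqrt(sum(((b$H1 - bpos) + (b$H2 - bpos))^2))
  w1 <- mk_water(s1, c(0, 0, 1))
  w2 <- mk_water(s2, c(0, 0, 1))
  w <- water_set(rbind(w1$O, w2$O, b$O), rbind(w1$H1, w2$H1, b$H1),
                 rbind(w1$H2, w2$H2, b$H2), rbind(w1$M, w2$M, b$M),
                 check = FALSE)
  fr <- frame(0, ions = sites(ctr, 1, "ION"), waters = w, box = box(L),
              wrap = FALSE)
  hb <- detect_hbonds(fr)
  expect_setequal(hb$acceptor[hb$donor == 3], c(1L, 2L))
  st <- shell_hbond_stats(trajectory(list(fr), dt = 1), shell = 2.0,
                          second_limit = 3.5)
  expect_equal(st$bridging_per_ion, 1)
})

test_that("statistics are invariant to water ordering and rigid rotation", {
  fr <- toy_water_box(15, box(10), seed = 13)
  hb1 <- detect_hbonds(fr)
  # permute the waters
  perm <- sample(15)
  w <- fr$waters
  wp <- water_set(w$O[perm, ], w$H1[perm, ], w$H2[perm, ], w$M[perm, ],
                  check = FALSE)
  frp <- frame(0, ions = NULL, waters = wp, box = fr$box, wrap = FALSE)
  hbp <- detect_hbonds(frp)
  expect_equal(nrow(hbp), nrow(hb1))
  # map permuted indices back and compare the bond sets
  inv <- order(perm)
  key1 <- sort(paste(hb1$donor, hb1$acceptor, round(hb1$distance, 9)))
  keyp <- sort(paste(perm[hbp$donor], perm[hbp$acceptor],
                     round(hbp$distance, 9)))
  expect_identical(key1, keyp)
})
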