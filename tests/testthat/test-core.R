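test_that("transactional-segment centre lies one stride ahead of the face", {
  expect_equal(unname(ts_centre(0, 0, 0, D = 30)[1, ]), c(30, 0))
  expect_equal(unname(ts_centre(0, 0, pi / 2, D = 30)[1, ]), c(0, 30),
               tolerance = 1e-12)
  expect_equal(unname(ts_centre(10, -5, pi, D = 20)[1, ]), c(-10, -5),
               tolerance = 1e-12)
  expect_error(ts_centre(NaN, 0, 0, D = 30), "non-finite")
  expect_error(ts_centre(0, 0, 0, D = -1))
})

test_that("unary cost is the squared distance from the TS centre", {
  params <- gcff_params(stride_D = 30, sigma = 80)
  # centre at the person's own TS centre: zero residual
  mu <- ts_centre(5, 7, 1.1, D = 30)
  expect_equal(unary_cost(5, 7, 1.1, mu[1, ], params), 0)
  # mu = (30, 0), centre 10 above it
  expect_equal(unary_cost(0, 0, 0, c(30, 10), params), 100)
  # 3-4-5 triangle from mu = (30, 0)
  expect_equal(unary_cost(0, 0, 0, c(33, 4), params), 25)
})

test_that("visibility cost follows the occlusion geometry", {
  params <- gcff_params(stride_D = 30, sigma = 80, vis_theta_hat = pi / 6,
                        vis_K = 1)
  # i closer than j: never occluded
  expect_equal(visibility_cost(c(0, 1), c(0, 2), c(0, 0), params), 0)
  # collinear, i behind j at distances 2 and 1: exp(1) * (2 - 1) / 1
  expect_equal(visibility_cost(c(0, 2), c(0, 1), c(0, 0), params), exp(1))
  # right angle between the two: outside the occlusion window
  expect_equal(visibility_cost(c(2, 0), c(0, 1), c(0, 0), params), 0)
  # exact equidistant tie (coincident persons) counts as closer: no penalty
  expect_equal(visibility_cost(c(0, 2), c(0, 2), c(0, 0), params), 0)
  # occluder on the centre: degenerate geometry
  expect_error(visibility_cost(c(0, 2), c(0, 0), c(0, 0), params),
               "degenerate")
})

test_that("per-person visibility penalty sums the pairwise costs", {
  params <- gcff_params(stride_D = 30, sigma = 80, vis_theta_hat = pi / 6,
                        vis_K = 2)
  solo <- gcff_scene(data.frame(id = "a", x = 3, y = 4, theta = 1))
  expect_equal(person_visibility_penalty(1, solo, c(0, 0), params), 0)

  # i strictly closest to the centre: every pair takes the closer branch
  sc <- gcff_scene(data.frame(id = c("a", "b", "c"),
                              x = c(1, 5, -7), y = c(0, 0, 0),
                              theta = 0))
  expect_equal(person_visibility_penalty(1, sc, c(0, 0), params), 0)

  # collinear trio, farthest person occluded by both others
  sc3 <- gcff_scene(data.frame(id = c("a", "b", "c"),
                               x = c(1, 2, 4), y = 0, theta = 0))
  expected <- exp(2) * (4 - 1) / 1 + exp(2) * (4 - 2) / 2
  expect_equal(person_visibility_penalty(3, sc3, c(0, 0), params), expected)
  # and matches a direct double loop over visibility_cost
  direct <- visibility_cost(c(4, 0), c(1, 0), c(0, 0), params) +
    visibility_cost(c(4, 0), c(2, 0), c(0, 0), params)
  expect_equal(person_visibility_penalty(3, sc3, c(0, 0), params), direct)
})

test_that("scene cost = residuals + MDL label cost + visibility", {
  params <- gcff_params(stride_D = 30, sigma = 80)
  one <- gcff_scene(data.frame(id = "a", x = 0, y = 0, theta = 0))
  a1 <- assign_labels(one, ts_centres(one, params = params), params)
  expect_equal(scene_cost(one, a1, params), params$sigma^2)

  # vis-a-vis pair at mutual distance 2D sharing the coincident TS point
  pair <- pair_scene(r = 0, D = 30)
  a2 <- structure(list(labels = c(a = 1L, b = 1L),
                       centres = matrix(c(0, 0), 1, 2,
                                        dimnames = list(NULL, c("u", "v"))),
                       energy = NA_real_),
                  class = "gcff_assignment")
  expect_equal(scene_cost(pair, a2, params), params$sigma^2)

  # TS centres 2r apart, shared midpoint centre: sigma^2 + 2 r^2
  r <- 45
  pair2 <- pair_scene(r = r, D = 30)
  a3 <- a2
  expect_equal(scene_cost(pair2, a3, params), params$sigma^2 + 2 * r^2)

  # a labelled person without a centre is inconsistent
  bad <- structure(list(labels = c(a = 2L, b = 2L),
                        centres = matrix(c(0, 0), 1, 2), energy = NA_real_),
                   class = "gcff_assignment")
  expect_error(scene_cost(pair, bad, params), "inconsistent|label")
})

test_that("costs are invariant under rigid motions of the scene", {
  set.seed(42)
  params <- gcff_params(stride_D = 30, sigma = 80)
  for (rep in 1:5) {
    sc <- random_scene(5)
    res <- gcff_detect(sc, params)
    ang <- stats::runif(1, -pi, pi)
    shift <- stats::runif(2, -500, 500)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    xy <- cbind(sc$x, sc$y) %*% t(R)
    sc2 <- gcff_scene(data.frame(id = sc$id,
                                 x = xy[, 1] + shift[1],
                                 y = xy[, 2] + shift[2],
                                 theta = norm_angle(sc$theta + ang)))
    res2 <- gcff_detect(sc2, params)
    expect_equal(res2$assignment$energy, res$assignment$energy,
                 tolerance = 1e-8)
    expect_true(groups_equal(res2$groups, res$groups))
    # centres transform by the same rigid motion
    c1 <- res$assignment$centres %*% t(R)
    c1 <- sweep(c1, 2, -shift)
    perm <- order(c1[, 1], c1[, 2])
    c2 <- res2$assignment$centres
    perm2 <- order(c2[, 1], c2[, 2])
    expect_equal(unname(c1[perm, , drop = FALSE]),
                 unname(c2[perm2, , drop = FALSE]), tolerance = 1e-6)
  }
})

test_that("scaling coordinates, D and sigma by s scales the energy by s^2", {
  set.seed(7)
  for (s in c(0.5, 3)) {
    sc <- random_scene(5)
    p1 <- gcff_params(stride_D = 30, sigma = 80)
    p2 <- gcff_params(stride_D = 30 * s, sigma = 80 * s)
    sc2 <- gcff_scene(data.frame(id = sc$id, x = sc$x * s, y = sc$y * s,
                                 theta = sc$theta))
    r1 <- gcff_detect(sc, p1)
    r2 <- gcff_detect(sc2, p2)
    expect_true(groups_equal(r1$groups, r2$groups))
    # the least-squares + MDL part scales exactly by s^2; the dimensionless
    # visibility part is scale-invariant, so compare with visibility off
    q1 <- gcff_params(stride_D = 30, sigma = 80, vis_theta_hat = 0)
    q2 <- gcff_params(stride_D = 30 * s, sigma = 80 * s, vis_theta_hat = 0)
    e1 <- gcff_detect(sc, q1)$assignment$energy
    e2 <- gcff_detect(sc2, q2)$assignment$energy
    expect_equal(e2, e1 * s^2, tolerance = 1e-8)
  }
})

test_that("energy decomposes: J >= mdl * labels, equality iff zero residuals", {
  params <- gcff_params(stride_D = 30, sigma = 80, vis_theta_hat = 0)
  set.seed(9)
  for (rep in 1:10) {
    sc <- random_scene(5)
    a <- assign_labels(sc, ts_centres(sc, params = params), params)
    k <- nrow(a$centres)
    expect_gte(a$energy, params$mdl_weight * k - 1e-9)
  }
  # zero-residual case achieves the bound exactly
  pair <- pair_scene(r = 0, D = 30)
  res <- gcff_detect(pair, params)
  expect_equal(res$assignment$energy, params$mdl_weight)
})

test_that("visibility penalty is non-negative on random geometry", {
  set.seed(12)
  params <- gcff_params(stride_D = 30, sigma = 80, vis_theta_hat = pi / 3,
                        vis_K = 2)
  for (rep in 1:50) {
    sc <- random_scene(4)
    ctr <- c(stats::runif(1, 0, 300), stats::runif(1, 0, 300))
    for (i in seq_len(nrow(sc))) {
      expect_gte(person_visibility_penalty(i, sc, ctr, params), 0)
    }
  }
})

test_that("angles are normalised to (-pi, pi] and ids must be unique", {
  sc <- gcff_scene(data.frame(id = "a", x = 0, y = 0, theta = 3 * pi))
  expect_equal(sc$theta, pi)
  expect_error(gcff_scene(data.frame(id = c("a", "a"), x = 0:1, y = 0,
                                     theta = 0)),
               "duplicate")
  expect_error(gcff_scene(data.frame(id = "a", x = "oops", y = 0, theta = 0)),
               "numeric")
})
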