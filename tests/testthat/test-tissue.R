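test_that("cuboid meshes have the exact element and node counts", {
  m <- build_cuboid_mesh(1.8, 1.8, 18, 0.3)
  expect_equal(nrow(m$elems), 2160)
  expect_equal(nrow(m$nodes), 2989)
  m1 <- build_cuboid_mesh(1, 1, 1, 1)
  expect_equal(nrow(m1$elems), 1); expect_equal(nrow(m1$nodes), 8)
  m2 <- build_cuboid_mesh(2, 1, 1, 1)
  expect_equal(nrow(m2$elems), 2); expect_equal(nrow(m2$nodes), 12)
  expect_error(build_cuboid_mesh(1.7, 1.8, 18, 0.3), "multiple")
})

test_that("conductivity tensor matches its closed form and transforms", {
  expect_equal(conductivity_tensor(c(1, 0, 0), 0.002, 1), 0.002 * diag(3))
  D <- conductivity_tensor(c(0, 0, 1), 0.0023, 0.35)
  expect_equal(D[3, 3], 0.0023)
  expect_equal(D[1, 1], 0.000805)
  expect_equal(D[2, 2], 0.000805)
  expect_true(all(D[upper.tri(D)] == 0))
  expect_true(all(eigen(D)$values > 0))
  # tensor transformation under rotation
  set.seed(2)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  n <- c(0, 0, 1)
  D_rot <- conductivity_tensor(as.numeric(R %*% n), 0.0023, 0.35)
  expect_equal(D_rot, R %*% D %*% t(R), tolerance = 1e-12)
  expect_error(conductivity_tensor(c(0, 0, 2)), "unit")
})

test_that("FEM stiffness is symmetric with zero row sums (no-flux)", {
  mesh <- build_cuboid_mesh(0.9, 0.9, 1.8, 0.3)
  fem <- arscore:::assemble_fem(mesh, monodomain_config())
  K <- as.matrix(fem$K)
  expect_equal(K, t(K), tolerance = 1e-14)
  # constants lie in the kernel: diffusing a uniform field does nothing
  expect_true(all(abs(rowSums(K)) < 1e-15))
  expect_equal(sum(fem$M), 0.09^2 * 0.18, tolerance = 1e-12) # total volume
})

test_that("a uniform resting state is invariant without stimulation", {
  mesh <- build_cuboid_mesh(0.6, 0.6, 0.9, 0.3)
  prot <- pacing_protocol(bcl = 20, n_beats = 1, n_recorded_beats = 1,
                          stim_amplitude = 0)
  st <- ord_limit_cycle_state(protocol = quick_protocol(30))
  res <- run_monodomain(mesh, prot, initial_states = st, record_every = 50)
  # spatially uniform at every recorded instant, to solver tolerance
  spread <- apply(res$v, 1, function(vv) diff(range(vv)))
  expect_true(all(spread < 1e-8))
  # integral of V over the domain conserved by pure diffusion steps
  expect_lt(abs(res$v[nrow(res$v), 1] - res$v[1, 1]), 0.5)
})

test_that("an end stimulus launches a monotone planar wave along z", {
  mesh <- build_cuboid_mesh(0.6, 0.6, 4.2, 0.3) # 3 x 3 x 15 nodes
  st <- ord_limit_cycle_state(protocol = quick_protocol(30))
  prot <- pacing_protocol(n_beats = 1, n_recorded_beats = 1)
  res <- run_monodomain(mesh, prot, initial_states = st)
  act <- res$activation[1, ]
  expect_true(all(!is.na(act))) # every node activates exactly once
  z <- mesh$nodes[, 3]
  mean_act <- tapply(act, z, mean)
  expect_true(all(diff(mean_act) > 0))
  # transverse anisotropy does not alter a planar longitudinal wave
  res_iso <- run_monodomain(mesh, prot, initial_states = st,
                            config = monodomain_config(r = 1))
  expect_equal(res_iso$activation[1, ], act, tolerance = 0.02)
})

test_that("conduction velocity decreases with longitudinal conductivity", {
  mesh <- build_cuboid_mesh(0.6, 0.6, 4.2, 0.3)
  st <- ord_limit_cycle_state(protocol = quick_protocol(30))
  prot <- pacing_protocol(n_beats = 1, n_recorded_beats = 1)
  cv <- vapply(c(0.0023, 0.0010), function(sig) {
    res <- run_monodomain(mesh, prot, initial_states = st,
                          config = monodomain_config(sigma_l = sig))
    conduction_velocity(res, beat = 1, z_range = c(0.2, 0.8))
  }, numeric(1))
  expect_gt(cv[1], cv[2])
})

test_that("node assignment permutes the accepted population reproducibly", {
  mesh <- build_cuboid_mesh(0.6, 0.6, 0.9, 0.3)
  scales <- lhs_sample(5, seed = 1)
  a1 <- assign_models(mesh, scales, seed = 4)
  a2 <- assign_models(mesh, scales, seed = 4)
  expect_identical(a1$model_of_node, a2$model_of_node)
  expect_equal(dim(a1$scalings), c(9, nrow(mesh$nodes)))
  # every model used at least once when the mesh is larger than the pool
  expect_setequal(unique(a1$model_of_node), 1:5)
})

test_that("tissue helpers expose faces, analysis nodes and cell count", {
  mesh <- build_cuboid_mesh(0.6, 0.6, 1.2, 0.3)
  zmin <- face_nodes(mesh, "zmin")
  expect_equal(length(zmin), 9)
  expect_true(all(mesh$nodes[zmin, 3] == 0))
  inner <- analysis_nodes(mesh)
  expect_true(!any(mesh$nodes[inner, 3] %in% c(0, 1.2)))
  # LV census scaled to the study cuboid, one significant figure
  expect_equal(estimate_cell_count(), 2e6)
  expect_equal(estimate_cell_count(0.05832, 3.2e9, 110), 2e6)
})
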