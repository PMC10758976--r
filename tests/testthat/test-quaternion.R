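# Quaternion algebra, relative joint rotation, and YXZ decomposition.

test_that("Hamilton product matches the rotation-matrix oracle", {
  expect_equal(quat_multiply(quaternion(1, 0, 0, 0), rotation_quat("z", 37)),
               rotation_quat("z", 37), tolerance = 1e-12)
  ab <- quat_multiply(rotation_quat("y", 30), rotation_quat("y", 60))
  expect_lt(quat_angle_deg(ab, rotation_quat("y", 90)), 1e-9)
  set.seed(101)
  for (i in 1:20) {
    q <- random_unit_quats(2)
    prod_ <- quat_multiply(q[1, ], q[2, ])
    expect_equal(rmat_from_quat(prod_),
                 rmat_from_quat(q[1, ]) %*% rmat_from_quat(q[2, ]),
                 tolerance = 1e-9)
  }
  expect_error(quat_multiply(c(1, 0, 0, NaN), c(1, 0, 0, 0)), "finite")
})

test_that("inverse is the conjugate and q (x) q^-1 is the identity", {
  expect_equal(quat_inverse(quaternion(1, 0, 0, 0)), quaternion(1, 0, 0, 0))
  expect_lt(quat_angle_deg(quat_inverse(rotation_quat("z", 45)),
                           rotation_quat("z", -45)), 1e-9)
  set.seed(102)
  qs <- random_unit_quats(50)
  for (i in seq_len(nrow(qs))) {
    r <- quat_multiply(qs[i, ], quat_inverse(qs[i, ]))
    expect_lt(quat_angle_deg(r, c(1, 0, 0, 0)), 1e-9)
  }
  expect_error(quat_inverse(c(0, 0, 0, 0)), "zero quaternion")
})

test_that("Hamilton product is associative on random triples", {
  set.seed(103)
  for (i in 1:30) {
    q <- random_unit_quats(3)
    lhs <- quat_multiply(quat_multiply(q[1, ], q[2, ]), q[3, ])
    rhs <- quat_multiply(q[1, ], quat_multiply(q[2, ], q[3, ]))
    expect_lt(quat_angle_deg(lhs, rhs), 1e-9)
  }
})

test_that("relative joint quaternion inverts the proximal operand", {
  set.seed(104)
  q <- random_unit_quats(1)[1, ]
  e <- euler_yxz(joint_quaternion(q, q))
  expect_equal(unname(e[1:3]), c(0, 0, 0), tolerance = 1e-9)
  j <- joint_quaternion(quaternion(1, 0, 0, 0), rotation_quat("y", 90))
  expect_lt(quat_angle_deg(j, rotation_quat("y", 90)), 1e-9)
  j2 <- joint_quaternion(rotation_quat("y", 30), rotation_quat("y", 120))
  expect_equal(rmat_from_quat(j2),
               t(rot_mat("y", 30)) %*% rot_mat("y", 120), tolerance = 1e-9)
})

test_that("YXZ decomposition round-trips and respects channel ranges", {
  expect_equal(unname(euler_yxz(quaternion(1, 0, 0, 0))[1:3]), c(0, 0, 0))
  expect_equal(unname(euler_yxz(rotation_quat("y", 45))[1:3]), c(45, 0, 0),
               tolerance = 1e-9)
  set.seed(105)
  qs <- random_unit_quats(1000)
  e <- euler_yxz(qs)
  expect_true(all(e$angle_y > -180 & e$angle_y <= 180 + 1e-9))
  expect_true(all(e$angle_x >= -90 - 1e-9 & e$angle_x <= 90 + 1e-9))
  qr <- euler_yxz_quat(e$angle_y, e$angle_x, e$angle_z)
  ## difference-norm angle: accurate for tiny discrepancies, unlike
  ## acos(dot) which saturates near 1e-6 deg in double precision
  d <- pmin(sqrt(rowSums((qr - qs)^2)), sqrt(rowSums((qr + qs)^2)))
  ang <- 2 * asin(pmin(1, d / 2)) * 180 / pi
  away <- abs(e$angle_x) < 89.9  # conditioning degrades near the singularity
  expect_lt(max(ang[away]), 1e-6)
  expect_lt(max(ang), 1e-3)
})

test_that("gimbal proximity is flagged and resolved with angle_z = 0", {
  q <- euler_yxz_quat(30, 90, 40)
  e <- euler_yxz(q)
  expect_true(attr(e, "gimbal"))
  expect_equal(unname(e[["angle_z"]]), 0)
  expect_equal(unname(e[["angle_x"]]), 90, tolerance = 1e-6)
  ## with x at 90 only y - z is observable; recomposition restores the rotation
  qr <- euler_yxz_quat(e[["angle_y"]], e[["angle_x"]], 0)
  expect_lt(quat_angle_deg(qr, q), 1e-6)
})

test_that("euler channel grows monotonically with the rotation angle", {
  angles <- seq(-170, 170, by = 10)
  for (axis in c("y", "z")) {
    got <- vapply(angles, function(a) {
      unname(euler_yxz(rotation_quat(axis, a))[[paste0("angle_", axis)]])
    }, numeric(1))
    expect_equal(got, angles, tolerance = 1e-9)
    expect_true(all(diff(got) > 0))
  }
  angles_x <- seq(-85, 85, by = 5)
  got_x <- vapply(angles_x, function(a) {
    unname(euler_yxz(rotation_quat("x", a))[["angle_x"]])
  }, numeric(1))
  expect_true(all(diff(got_x) > 0))
})

test_that("canonicalization and sign alignment behave", {
  q <- quat_canonical(-rotation_quat("y", 40))
  expect_gte(q[["w"]], 0)
  set.seed(106)
  stream <- rotation_quat("y", seq(0, 120, length.out = 50))
  stream[seq(5, 50, by = 7), ] <- -stream[seq(5, 50, by = 7), ]
  aligned <- sign_align(stream)
  dots <- rowSums(aligned[-1, ] * aligned[-nrow(aligned), ])
  expect_true(all(dots >= 0))
})

test_that("angular speed recovers a constant rotation rate", {
  fs <- 96
  ang <- seq(0, 200, by = 120 / fs)  # 120 deg/s about z
  stream <- rotation_quat("z", ang)
  v <- angular_speed(stream, fs)
  expect_equal(v, rep(120, length(ang)), tolerance = 1e-6)
  expect_error(angular_speed(stream[1, , drop = FALSE], fs), "2 frames")
})
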