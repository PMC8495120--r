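test_that("maternal body weight passes through the measured study means", {
  expect_equal(maternal_body_weight(0, default_phys), 0.277)
  expect_equal(maternal_body_weight(15, default_phys), 0.356)
  expect_equal(maternal_body_weight(20, default_phys), 0.422)
  bw <- maternal_body_weight(seq(0, 20, by = 0.1), default_phys)
  expect_true(all(diff(bw) >= 0))
  expect_error(maternal_body_weight(-1), "0, 20")
  expect_error(maternal_body_weight(21), "0, 20")
})

test_that("tissue volumes match the parameter table and its conventions", {
  expect_equal(volumes_at(0, default_phys)[["placenta"]], 0)
  expect_equal(volumes_at(20, default_phys)[["placenta"]], 0.167)
  expect_equal(volumes_at(0, default_phys)[["liver"]], 0.0351 * 0.277)
  # constant-fraction tissues do not grow with maternal BW
  expect_equal(volumes_at(18, default_phys)[["liver"]],
               volumes_at(0, default_phys)[["liver"]])
  # slowly perfused volume is the balance of the named fractions
  fv <- default_phys$frac_volumes
  expect_equal(volumes_at(3, default_phys)[["slowly_perfused"]],
               (1 - sum(fv) ) * 0.277)
  # capillary/cellular split respects the blood-volume fractions
  v <- volumes_at(10, default_phys, split_blood = TRUE)
  expect_equal(v[["kidney_blood"]], 0.16 * v[["kidney"]])
  expect_equal(v[["kidney_blood"]] + v[["kidney_cell"]], v[["kidney"]])
})

test_that("blood flows close the cardiac-output balance", {
  q0 <- flows_at(0, default_phys)
  expect_equal(q0[["placenta"]], 0)
  expect_equal(q0[["cardiac_output"]], 24.56 * 0.277)
  expect_equal(flows_at(20, default_phys)[["mammary"]], 0.064)
  for (gd in c(0, 5, 12, 20)) {
    q <- flows_at(gd, default_phys)
    draws <- sum(q[c("gi", "liver_arterial", "muscle", "brain", "kidney",
                     "slowly_perfused", "mammary", "fat", "placenta",
                     "rapidly_perfused")])
    expect_equal(draws, q[["cardiac_output"]])
  }
})

test_that("volumes and flows are non-negative and continuous over gestation", {
  grid <- seq(0, 20, by = 0.1)
  prev_v <- NULL; prev_q <- NULL
  for (gd in grid) {
    v <- volumes_at(gd, default_phys)
    q <- flows_at(gd, default_phys)
    expect_true(all(v >= 0))
    expect_true(all(q >= 0))
    if (!is.null(prev_v)) {
      expect_lt(max(abs(v - prev_v)), 0.02)
      expect_lt(max(abs(q - prev_q)), 0.2)
    }
    prev_v <- v; prev_q <- q
  }
})

test_that("fetal physiology grows to its endpoints and scales with litter size", {
  f20 <- fetal_physiology_at(20, default_phys)
  expect_equal(f20$per_fetus[["bw"]], 0.0068)
  # brain and liver endpoints are litter totals at the reference litter
  expect_equal(f20$litter$volumes[["brain"]], 0.0034)
  expect_equal(f20$litter$volumes[["liver"]], 0.0044)
  expect_equal(f20$litter$bw, 13.5 * 0.0068)
  expect_gt(f20$per_fetus[["rest_of_body"]], 0)
  expect_equal(f20$litter$flows[["cardiac_output"]], 22.8 * 13.5 * 0.0068)
  # before conceptus onset everything is zero
  f3 <- fetal_physiology_at(3, default_phys)
  expect_true(all(f3$litter$volumes == 0))
  # litter totals are linear in litter size
  f10 <- fetal_physiology_at(18, default_phys, n_fetuses = 10)
  f20n <- fetal_physiology_at(18, default_phys, n_fetuses = 20)
  expect_equal(2 * f10$litter$volumes, f20n$litter$volumes)
  expect_equal(2 * f10$litter$flows, f20n$litter$flows)
})
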