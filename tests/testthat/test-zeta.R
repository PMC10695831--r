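buffer <- list(salt_mono_M = 0.1, salt_di_M = 0, pH = 8.5, rh_nm = 60,
               temp_C = 25)

test_that("featurization mixes charge and Tm correctly", {
  f <- featurize_liposome(c(DMPC = 1), buffer)
  expect_equal(f$mean_charge, 0)
  expect_equal(f$mean_tm_C, 24)

  f <- featurize_liposome(c(DMPC = 0.5, DMPG = 0.5), buffer)
  expect_equal(f$mean_charge, -0.5)
  expect_equal(f$mean_tm_C, 23.5)

  # cholesterol excluded from the Tm average, counted in its own feature
  f <- featurize_liposome(c(DMPC = 0.8, cholesterol = 0.2), buffer)
  expect_equal(f$chol_frac, 0.2)
  expect_equal(f$mean_tm_C, 24)

  expect_error(featurize_liposome(c(DMPC = 0.5, DXPX = 0.5), buffer), "DXPX")
})

test_that("inverse-error weights span exactly 0.375 to 0.625", {
  expect_equal(weights_from_sd(c(1, 3)), c(0.625, 0.375))
  expect_equal(weights_from_sd(c(2, 2, 2)), c(0.5, 0.5, 0.5))
  # affine interpolation oracle: equally spaced sds -> equally spaced weights
  expect_equal(weights_from_sd(c(1, 2, 3)), c(0.625, 0.5, 0.375))
  expect_equal(weights_from_sd(c(0, 1, 4)), 0.625 - 0.25 * c(0, 1, 4) / 4)
  # missing sds get the midpoint
  expect_equal(weights_from_sd(c(1, NA, 3)), c(0.625, 0.5, 0.375))
  expect_error(weights_from_sd(c(-1, 2)), "non-negative")
})

test_that("literature inclusion predicates filter the training table", {
  tab <- data.frame(mean_tm_C = c(24, NA, 24, 24),
                    salt_type = c("NaCl", "NaCl", "CaCl2", "KCl"),
                    ethanol = c(0, 0, 0, 0.1))
  expect_equal(nrow(filter_zeta_table(tab)), 1)
})

small_cfg <- function(...) {
  zeta_training_config(ensemble_size = 3, max_rounds = 300, seed = 7, ...)
}

test_that("a small ensemble learns a planted charge effect", {
  z <- gen_zeta_table(n = 120, effects = list(mean_charge = 30),
                      noise_sd = 1, seed = 3)
  m <- train_zeta_ensemble(z$table, small_cfg())
  expect_length(m$members, 3)
  expect_true(all(m$member_mae < 5))

  q <- z$table[rep(1, 2), ]
  q$mean_charge <- c(-1, 0)
  pred <- predict(m, q)
  expect_lt(abs(pred[1] - (-30)), 3)
  expect_lt(abs(pred[2] - 0), 3)
})

test_that("training is reproducible and prediction averages members", {
  z <- gen_zeta_table(n = 80, effects = list(mean_charge = 30),
                      noise_sd = 1, seed = 5)
  m1 <- train_zeta_ensemble(z$table, small_cfg())
  m2 <- train_zeta_ensemble(z$table, small_cfg())
  expect_equal(round(m1$cv$mean_mae, 3), round(m2$cv$mean_mae, 3))
  expect_equal(predict(m1, z$table[1:5, ]), predict(m2, z$table[1:5, ]))

  # ensemble of one predicts exactly its single member
  m <- train_zeta_ensemble(z$table,
                           zeta_training_config(ensemble_size = 1,
                                                max_rounds = 300, seed = 7))
  X <- asymfold:::zeta_feature_matrix(z$table[1:5, ])
  expect_equal(predict(m, z$table[1:5, ]),
               as.numeric(predict(m$members[[1]], X)))
})

test_that("a constant target is reproduced almost exactly", {
  expect_warning(
    z <- gen_zeta_table(n = 60, effects = list(mean_charge = 0),
                        noise_sd = 0, seed = 9),
    "degenerate")
  tab <- z$table
  tab$zeta_mV <- -20
  m <- train_zeta_ensemble(tab, small_cfg())
  expect_true(all(abs(predict(m, tab[1:10, ]) - (-20)) < 1e-6))
})

test_that("a constant feature earns zero gain", {
  z <- gen_zeta_table(n = 100, effects = list(mean_charge = 30),
                      noise_sd = 1, seed = 11)
  tab <- z$table
  tab$chol_frac <- 0.1
  m <- train_zeta_ensemble(tab, small_cfg())
  imp <- zeta_importance(m, ablate = FALSE)
  expect_equal(imp$gain$max[imp$gain$feature == "chol_frac"], 0)
  expect_equal(which.max(imp$gain$median),
               which(imp$gain$feature == "mean_charge"))
})

test_that("predictions cannot beat the measurement noise floor", {
  z <- gen_zeta_table(n = 150, effects = list(mean_charge = 30),
                      noise_sd = 1.5, seed = 13)
  m <- train_zeta_ensemble(z$table, small_cfg())
  # expected MAE of noise alone is sd*sqrt(2/pi)
  expect_gt(m$cv$mean_mae, 1.5 * sqrt(2 / pi) - 0.35)
})
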