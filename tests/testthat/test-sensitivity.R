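# Additive test model with known variance decomposition: for
# y = sum a_i x_i with x_i uniform on ranges of width r_i, the first-order
# index of x_i is a_i^2 r_i^2 / sum_j a_j^2 r_j^2.
additive_readout <- function(a) {
  function(X, dose) {
    y <- as.vector(X %*% a)
    matrix(y, ncol = 1, dimnames = list(NULL, "y"))
  }
}

additive_truth <- function(a, ranges) {
  contrib <- a^2 * (ranges$max - ranges$min)^2
  contrib / sum(contrib)
}

test_that("eFAST recovers analytic variance fractions for an additive model", {
  a <- c(4, 2, 1, 0.5)
  ranges <- data.frame(parameter = paste0("x", 1:4),
                       min = c(0, 0, 0, 0), max = c(1, 2, 1, 1))
  design <- rci_sens_design(NS = 513, NR = 8, doses = 0, seed = 2)
  rep <- efast_indices(design, ranges, additive_readout(a))
  truth <- additive_truth(a, ranges)
  si_mean <- apply(rep$Si[1:4, 1, 1, ], 1, mean)
  expect_equal(unname(si_mean), truth, tolerance = 0.05)
  ## the dummy's indices calibrate estimator noise near zero
  expect_lt(mean(rep$Si["dummy", 1, 1, ]), 0.01)
  expect_lt(mean(rep$STi["dummy", 1, 1, ]), 0.05)
  ## total order bounds first order up to estimator noise
  noise <- 2 * stats::sd(rep$STi["dummy", 1, 1, ]) + 0.02
  expect_true(all(rep$STi[1:4, 1, 1, ] >= rep$Si[1:4, 1, 1, ] - noise))
})

test_that("a single-factor readout concentrates all variance on it", {
  ranges <- data.frame(parameter = c("x1", "x2", "x3"),
                       min = 0, max = 1)
  design <- rci_sens_design(NS = 257, NR = 4, doses = 0, seed = 5)
  rep <- efast_indices(design, ranges, additive_readout(c(1, 0, 0)))
  expect_gt(mean(rep$STi["x1", 1, 1, ]), 0.9)
  expect_lt(mean(rep$STi["x2", 1, 1, ]), 0.05)
  expect_lt(mean(rep$Si["x3", 1, 1, ]), 0.01)
})

test_that("failed readout points are excluded with a warning", {
  ranges <- data.frame(parameter = "x1", min = 0, max = 1)
  design <- rci_sens_design(NS = 65, NR = 2, doses = 0, seed = 1)
  readout <- function(X, dose) {
    y <- X[, 1]
    y[seq(1, length(y), by = 30)] <- NA  # sporadic failures
    matrix(y, ncol = 1, dimnames = list(NULL, "y"))
  }
  expect_warning(rep <- efast_indices(design, ranges, readout), "excluded")
  expect_true(all(is.finite(rep$Si["x1", 1, 1, ])))
})

# Hand-built index report: k parameters whose resample distributions either
# match the dummy's or sit clearly above it.
fake_report <- function(shifted, n_par = 4, NR = 12, seed = 1) {
  set.seed(seed)
  pars <- c(paste0("p", seq_len(n_par)), "dummy")
  dims <- list(parameter = pars, output = "y", dose = "0",
               resample = as.character(seq_len(NR)))
  Si <- array(NA_real_, lengths(dims), dims)
  for (pp in pars) {
    mu <- if (pp %in% shifted) 0.4 else 0.02
    Si[pp, 1, 1, ] <- pmax(rnorm(NR, mu, 0.02), 0)
  }
  STi <- Si + 0.05
  structure(list(Si = Si, STi = STi,
                 design = rci_sens_design(NS = 65, NR = NR, doses = 0,
                                          alpha = 0.05),
                 ranges = data.frame(parameter = setdiff(pars, "dummy"),
                                     min = 0, max = 1),
                 has_dummy = TRUE),
            class = "rci_sens_report")
}

test_that("MeFAST battery separates shifted from dummy-like parameters", {
  rep <- mefast_tests(fake_report(shifted = c("p1", "p3")))
  tt <- rep$tests
  for (pp in c("p1", "p3")) {
    rows <- tt[tt$parameter == pp & tt$index == "Si", ]
    expect_true(all(rows$p_t < 0.05))
    expect_true(all(rows$p_wilcoxon < 0.05))
  }
  for (pp in c("p2", "p4")) {
    rows <- tt[tt$parameter == pp, ]
    expect_true(all(rows$n_significant <= 1))
  }
})

test_that("test outcomes are invariant to parameter ordering", {
  rep <- fake_report(shifted = "p2")
  perm <- c("p3", "p1", "p4", "p2", "dummy")
  rep2 <- rep
  rep2$Si <- rep$Si[perm, , , , drop = FALSE]
  rep2$STi <- rep$STi[perm, , , , drop = FALSE]
  t1 <- mefast_tests(rep)$tests
  t2 <- mefast_tests(rep2)$tests
  t1 <- t1[order(t1$parameter, t1$index), ]
  t2 <- t2[order(t2$parameter, t2$index), ]
  expect_equal(t1$n_significant, t2$n_significant)
  expect_equal(t1$p_t, t2$p_t, tolerance = 1e-12)
})

test_that("classification recovers an engineered influential subset", {
  rep <- mefast_tests(fake_report(shifted = c("p1", "p4"), n_par = 5))
  cls <- classify_parameters(rep)
  expect_setequal(cls$estimate, c("p1", "p4"))
  expect_setequal(cls$fix, c("p2", "p3", "p5"))
  ## all-significant and never-significant extremes
  all_sig <- mefast_tests(fake_report(shifted = paste0("p", 1:4)))
  expect_length(classify_parameters(all_sig)$fix, 0)
  none_sig <- mefast_tests(fake_report(shifted = character(0)))
  expect_length(classify_parameters(none_sig)$estimate, 0)
})

test_that("designs below the interference limit or without resamples fail", {
  expect_error(rci_sens_design(NS = 64), "at least")
  rep <- fake_report(shifted = "p1", NR = 1)
  expect_error(mefast_tests(rep), "resamples")
})

test_that("full-model readout exposes state variables at chosen days", {
  p <- rci_default_params()
  readout <- rci_model_readout(p, variables = c("Dam_tb", "N_tb"),
                               days = c(1, 3),
                               solver = rci_solver_options(dt = 0.5))
  X <- matrix(c(p[["snr"]], p[["knd"]]), nrow = 1,
              dimnames = list(NULL, c("snr", "knd")))
  Y <- readout(X, 0)
  expect_equal(colnames(Y),
               c("Dam_tb@day1", "Dam_tb@day3", "N_tb@day1", "N_tb@day3"))
  ## matches a direct simulation of the same scenario
  expo <- rci_exposure(severity = "superficial", DR = 0)
  traj <- simulate_rci(build_initial_state(expo, p), p, expo, horizon = 96,
                       solver = rci_solver_options(dt = 0.5))
  expect_equal(unname(Y[1, "Dam_tb@day3"]),
               unname(traj$states[match(72, traj$times), "Dam_tb"]))
})
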