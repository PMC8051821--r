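test_that("all four algorithms separate an easy training set perfectly", {
  tab <- gen_feature_table(10, 14, 2, shift = 6, n_shifted = 2, seed = 1)
  for (alg in c("SVM", "LDA", "KNN", "DT")) {
    m <- train_classifier(tab, classifier_spec(alg))
    expect_equal(unname(evaluate_model(m, tab)), c(1, 1, 1),
                 info = alg)
  }
})

test_that("conflicting duplicate rows cap training accuracy below 1", {
  tab <- gen_feature_table(4, 4, 3, seed = 2)
  conflict <- tab
  conflict$group <- rev(tab$group) # same X, opposite labels after rbind
  both <- rbind(tab, conflict)
  both$subject_id <- sprintf("s%03d", seq_len(nrow(both)))
  for (alg in c("SVM", "LDA")) {
    m <- train_classifier(both, classifier_spec(alg))
    expect_lt(evaluate_model(m, both)[["accuracy"]], 1)
  }
})

test_that("training and prediction are deterministic under a seed", {
  tab <- gen_feature_table(6, 6, 4, shift = 0.5, n_shifted = 2, seed = 3)
  for (alg in c("SVM", "LDA", "KNN", "DT")) {
    p1 <- predict(train_classifier(tab, classifier_spec(alg, seed = 5)), tab)
    p2 <- predict(train_classifier(tab, classifier_spec(alg, seed = 5)), tab)
    expect_identical(p1, p2, info = alg)
  }
})

test_that("degenerate and inverted predictors give the known arithmetic", {
  truth <- rep(c("ACA", "CONTROL"), c(10, 14))
  all_aca <- evaluate_predictions(rep("ACA", 24), truth)
  expect_equal(round(all_aca[["accuracy"]], 3), 0.417)
  expect_equal(all_aca[["sensitivity"]], 1)
  expect_equal(all_aca[["specificity"]], 0)
  all_ctl <- evaluate_predictions(rep("CONTROL", 24), truth)
  expect_equal(all_ctl[["accuracy"]], 14 / 24)
  expect_equal(all_ctl[["sensitivity"]], 0)
  expect_equal(all_ctl[["specificity"]], 1)
  perfect <- evaluate_predictions(truth, truth)
  expect_equal(unname(perfect), c(1, 1, 1))
})

test_that("training rejects single-class and missing-value inputs", {
  tab <- gen_feature_table(4, 4, 3, seed = 4)
  solo <- tab[tab$group == "ACA", ]
  expect_error(train_classifier(solo, classifier_spec("LDA")),
               "single class")
  expect_error(train_classifier(cbind(feature_matrix(tab), NA),
                                classifier_spec("SVM"), y = tab$group),
               "missing")
  m <- train_classifier(tab, classifier_spec("KNN"))
  expect_error(predict(m, tab[c("subject_id", "session_id", "group")]),
               "absent|lacks")
})

test_that("the validation suite produces five schemes plus consistent averages", {
  tt <- toy_session_tables(seed = 5)
  rep <- validation_suite(tt$rs1, tt$rs2)
  expect_equal(nrow(rep), 4 * 6)
  expect_setequal(unique(rep$scheme),
                  c("TRAIN_RS1_VAL_RS2", "TRAIN_RS2_VAL_RS1", "LOOCV_RS1",
                    "LOOCV_RS2", "LOOCV_CONCAT", "Average"))
  for (alg in unique(rep$algorithm)) {
    sub <- rep[rep$algorithm == alg, ]
    expect_equal(sub$accuracy[sub$scheme == "Average"],
                 mean(sub$accuracy[sub$scheme != "Average"]),
                 tolerance = 1e-12)
  }
  # accuracy identity holds exactly on every row (10 ACA, 14 controls)
  expect_equal(rep$accuracy,
               (rep$sensitivity * 10 + rep$specificity * 14) / 24,
               tolerance = 1e-12)
  # swapping the sessions swaps the two transfer rows
  rep_sw <- validation_suite(tt$rs2, tt$rs1)
  for (alg in unique(rep$algorithm)) {
    a <- rep[rep$algorithm == alg, ]; b <- rep_sw[rep_sw$algorithm == alg, ]
    expect_equal(b$accuracy[b$scheme == "TRAIN_RS1_VAL_RS2"],
                 a$accuracy[a$scheme == "TRAIN_RS2_VAL_RS1"])
    expect_equal(b$accuracy[b$scheme == "LOOCV_CONCAT"],
                 a$accuracy[a$scheme == "LOOCV_CONCAT"])
  }
  # subject mismatch is an error
  other <- tt$rs2; other$subject_id <- paste0("x", other$subject_id)
  expect_error(validation_suite(tt$rs1, other), "same subjects")
})

test_that("select_best ranks by accuracy with sensitivity tie-breaks", {
  mk <- function(acc, sens) {
    r <- data.frame(algorithm = "SVM",
                    scheme = c(rsndyn:::VALIDATION_SCHEMES, "Average"),
                    accuracy = acc, sensitivity = sens, specificity = 0.5)
    class(r) <- c("validation_report", "data.frame")
    r
  }
  one <- select_best(mk(0.9, 0.8))
  expect_equal(one$avg_accuracy, 0.9)
  two <- select_best(list(a = mk(0.90, 0.8), b = mk(0.85, 0.9)))
  expect_equal(two$setup, "a")
  tie <- select_best(list(lo = mk(0.9, 0.7), hi = mk(0.9, 0.8)))
  expect_equal(tie$setup, "hi")
  tie2 <- select_best(list(z = mk(0.9, 0.8), a = mk(0.9, 0.8)))
  expect_equal(tie2$setup, "a")
})

test_that("feature name parsing finds network involvement", {
  feats <- c("In-EP_DMN", "sFC-MVISU-DMN", "netgc_DMN->AUDI",
             "ip_MVISU-DMN_s2", "GC_NetDeg_DAN", "sFC-CB-FPL",
             "lead_AUDI-FPR_s1")
  hit <- feature_involves(feats, c("DMN", "DAN", "SN"))
  expect_identical(hit, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("subset refinement respects its admission criteria and bounds", {
  tt <- toy_session_tables(n_features = 6, shift = 3, n_shifted = 1, seed = 6)
  # rename features so exactly three involve admissible networks
  nm <- c("In-EP_DMN", "sFC-DMN-VAN", "GC_NetDeg_SN", "f_noise1", "f_noise2",
          "f_noise3")
  names(tt$rs1)[-(1:3)] <- nm; names(tt$rs2)[-(1:3)] <- nm
  specs <- list(DT = classifier_spec("DT"), LDA = classifier_spec("LDA"))
  r0 <- refine_subsets(tt$rs1, tt$rs2, nm, specs = specs, max_iter = 0)
  expect_setequal(r0$subsets$network,
                  c("In-EP_DMN", "sFC-DMN-VAN", "GC_NetDeg_SN"))
  expect_identical(r0$subsets$network_refined, r0$subsets$network)
  expect_equal(nrow(r0$trace), 0)
  r1 <- refine_subsets(tt$rs1, tt$rs2, nm, specs = specs, max_iter = 1)
  expect_true(all(unlist(r1$subsets) %in% nm))
  # the informative feature (renamed to In-EP_DMN) survives refinement
  expect_true("In-EP_DMN" %in% r1$subsets$network_refined)
})

test_that("leave-one-subject-out holds out both sessions of a subject", {
  tt <- toy_session_tables(n_a = 5, n_b = 5, shift = 3, seed = 7)
  concat <- rbind(tt$rs1, tt$rs2)
  m <- loso_metrics(concat, classifier_spec("LDA"))
  expect_named(m, c("accuracy", "sensitivity", "specificity"))
  expect_true(all(m >= 0 & m <= 1))
  expect_gt(m[["accuracy"]], 0.7) # well-separated toy groups
})
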