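test_that("contact sets equal brute force and respect rigid invariance", {
  ref <- make_reference_complex(seed = 21)
  expect_equal(contact_set(ref), brute_contacts(ref))

  far <- grappi:::transform_structure(ref, diag(3), c(0, 0, 40), chain = "B")
  expect_length(contact_set(far), 0)

  # hand-placed: exactly 4 cross-chain pairs within 5 A
  s <- toy_structure(list(
    list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, xyz = c(10, 0, 0)),
    list(chain = "A", resno = 3, xyz = c(20, 0, 0)),
    list(chain = "A", resno = 4, xyz = c(30, 0, 0)),
    list(chain = "B", resno = 1, xyz = c(0, 4.9, 0)),
    list(chain = "B", resno = 2, xyz = c(10, 4.9, 0)),
    list(chain = "B", resno = 3, xyz = c(20, 4.9, 0)),
    list(chain = "B", resno = 4, xyz = c(30, 4.9, 0))))
  expect_equal(contact_set(s),
               c("A:1:+B:1:", "A:2:+B:2:", "A:3:+B:3:", "A:4:+B:4:"))

  tr <- random_rigid()
  s2 <- grappi:::transform_structure(s, tr$R, tr$t)
  expect_equal(contact_set(s2), contact_set(s))
})

test_that("fnat attains its cap on the reference and drops as designed", {
  ref <- make_reference_complex(seed = 22)
  expect_equal(fnat(ref, ref), 1.0)

  gone <- grappi:::transform_structure(ref, diag(3), c(50, 0, 0), chain = "B")
  expect_equal(fnat(gone, ref), 0.0)

  # exactly half the native contacts preserved by construction
  s <- toy_structure(list(
    list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, xyz = c(15, 0, 0)),
    list(chain = "B", resno = 1, xyz = c(0, 4, 0)),
    list(chain = "B", resno = 2, xyz = c(15, 4, 0))))
  half <- toy_structure(list(
    list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, xyz = c(15, 0, 0)),
    list(chain = "B", resno = 1, xyz = c(0, 4, 0)),
    list(chain = "B", resno = 2, xyz = c(15, 30, 0))))
  expect_length(contact_set(s), 2)
  expect_equal(fnat(half, s), 0.5)

  sep <- toy_structure(list(
    list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
    list(chain = "B", resno = 1, xyz = c(0, 40, 0))))
  expect_error(fnat(ref, sep), "zero cross-chain contacts",
               class = "grappi_usage_error")
})

test_that("superposition is exact for rigid copies and matches bio3d and a grid oracle", {
  set.seed(23)
  P <- matrix(rnorm(30), 10, 3)
  expect_lt(superpose(P, P)$rmsd, 1e-9)

  tr <- random_rigid()
  Q <- sweep(P %*% tr$R, 2, tr$t, "+")
  sp <- superpose(P, Q)
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  # noisy 4-point sets: compare with bio3d's least-squares fit and with an
  # exhaustive rotation grid search
  for (k in 1:2) {
    A <- matrix(rnorm(12, sd = 3), 4, 3)
    B <- sweep(A %*% random_rigid()$R, 2, rnorm(3), "+") +
      matrix(rnorm(12, sd = 0.3), 4, 3)
    ours <- superpose(A, B)$rmsd
    fit <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.numeric(t(B)), mobile = as.numeric(t(A))))
    b3d <- sqrt(mean(colSums(matrix(fit - as.numeric(t(B)), nrow = 3)^2)))
    expect_equal(ours, b3d, tolerance = 1e-6)
    expect_equal(ours, superpose_grid_oracle(A, B), tolerance = 1e-3)
  }

  expect_error(superpose(P[1:2, ], Q[1:2, ]), class = "grappi_usage_error")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate",
               class = "grappi_usage_error")
})

test_that("iRMSD and lRMSD vanish on the reference and ignore global motion", {
  ref <- make_reference_complex(seed = 24)
  expect_lt(irmsd(ref, ref), 1e-9)
  expect_lt(lrmsd(ref, ref), 1e-9)

  tr <- random_rigid()
  moved <- grappi:::transform_structure(ref, tr$R, tr$t)
  expect_lt(irmsd(moved, ref), 1e-6)
  expect_lt(lrmsd(moved, ref), 1e-6)
})

test_that("RMSD values match direct computation on known perturbations", {
  ref <- make_reference_complex(seed = 25)
  # ligand rotated about its own center: lRMSD equals the direct formula on
  # receptor-aligned coordinates (receptor untouched => alignment is identity)
  lig <- ref$atoms$chain == "B"
  ctr <- colMeans(coords(ref)[lig, ])
  R <- grappi:::rotation_matrix(c(0, 0, 1), 10)
  dec <- grappi:::transform_structure(ref, R, c(0, 0, 0), chain = "B",
                                      center = ctr)
  bb <- lig & ref$atoms$atom %in% c("N", "CA", "C", "O")
  direct <- sqrt(mean(rowSums((coords(dec)[bb, ] - coords(ref)[bb, ])^2)))
  expect_equal(lrmsd(dec, ref), direct, tolerance = 1e-6)

  # one interface residue displaced 2 A, remainder fixed: iRMSD equals the
  # Kabsch residual computed independently via bio3d on the same atom set
  M <- grappi:::cross_residue_min_dist(ref)
  ikeys <- c(rownames(M)[apply(M, 1, min) <= 10],
             colnames(M)[apply(M, 2, min) <= 10])
  mod <- ref
  k1 <- ikeys[1]
  sel <- residue_keys(ref) == k1
  mod$atoms$z[sel] <- mod$atoms$z[sel] + 2
  mb <- grappi:::matched_backbone(mod, ref, ikeys)
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(mb$reference)),
                   mobile = as.numeric(t(mb$model))))
  b3d <- sqrt(mean(colSums(matrix(fit - as.numeric(t(mb$reference)),
                                  nrow = 3)^2)))
  expect_equal(irmsd(mod, ref), b3d, tolerance = 1e-6)
})

test_that("CAPRI classes follow the threshold table and are monotone", {
  expect_equal(capri_class(1.0, 0, 0), "high")
  expect_equal(capri_class(0.05, 20, 30), "incorrect")
  expect_equal(capri_class(0.35, 1.8, 6.0), "medium")
  expect_equal(capri_class(0.15, 3.5, 12), "acceptable")

  # improving any single metric never demotes the class
  rank <- c(incorrect = 0, acceptable = 1, medium = 2, high = 3)
  set.seed(26)
  for (k in 1:200) {
    f <- runif(1); ir <- runif(1, 0, 12); lr <- runif(1, 0, 15)
    base <- rank[capri_class(f, ir, lr)]
    expect_gte(rank[capri_class(min(f + runif(1, 0, 0.3), 1), ir, lr)], base)
    expect_gte(rank[capri_class(f, max(ir - runif(1, 0, 3), 0), lr)], base)
    expect_gte(rank[capri_class(f, ir, max(lr - runif(1, 0, 4), 0))], base)
  }
})

test_that("fnat binarization uses an inclusive 0.3 threshold", {
  expect_equal(binarize_fnat(c(0.29, 0.30, 0.31)), c(0L, 1L, 1L))
})

test_that("class weights are inversely proportional to class counts", {
  labels <- c(rep(0, 90), rep(1, 10))
  w <- class_weights(labels)
  expect_equal(unname(w["0"]), 0.1)
  expect_equal(unname(w["1"]), 0.9)
  expect_equal(sum(w), 1)
  wb <- class_weights(c(0, 0, 1, 1))
  expect_equal(unname(wb["0"]), unname(wb["1"]))
  expect_error(class_weights(rep(1, 5)), class = "grappi_usage_error")
})

test_that("decoy quality metrics trend with perturbation magnitude", {
  ref <- make_reference_complex(seed = 27)
  dec <- make_decoys(ref, levels = c(0.5, 3, 10), n_per_level = 50, seed = 28)
  med_f <- med_l <- numeric(0)
  for (lv in unique(dec$manifest$level)) {
    ids <- dec$manifest$id[dec$manifest$level == lv]
    med_f <- c(med_f, median(vapply(dec$structures[ids], fnat, numeric(1),
                                    reference = ref)))
    med_l <- c(med_l, median(vapply(dec$structures[ids], lrmsd, numeric(1),
                                    reference = ref)))
  }
  expect_true(all(diff(med_f) <= 0))
  expect_true(all(diff(med_l) >= 0))
})
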