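test_that("clustered selection consumes clusters in descending-size order", {
  # clusters of size 5 (stem run) and 3 (patch block), well separated
  cm <- contact_map(40, rbind(
    cbind(5:9, 35:31),                  # 5-cell anti-diagonal run
    rbind(c(20, 30), c(20, 31), c(21, 30)))) # 3-cell block
  part <- find_clusters(cm)
  expect_equal(part$sizes, c(5L, 3L))
  big <- paste(part$clusters[[1]][, 1], part$clusters[[1]][, 2])
  s5 <- select_clustered(cm, 5, seed = 1)
  expect_setequal(paste(s5$chosen[, 1], s5$chosen[, 2]), big)
  s6 <- select_clustered(cm, 6, seed = 1)
  k6 <- paste(s6$chosen[, 1], s6$chosen[, 2])
  expect_true(all(big %in% k6)) # 5 from the largest + 1 from the next
  expect_equal(sum(!k6 %in% big), 1L)
  s8 <- select_clustered(cm, 8, seed = 1)
  expect_equal(s8$chosen, cm$contacts) # n = |contacts| returns everything
  expect_equal(s8$lambda, 0)
  expect_error(select_clustered(cm, 9, seed = 1), "only 8")
})

test_that("random selection is uniform, seeded and reproducible", {
  cm <- random_contact_map(60, 30, seed = 4)
  a <- select_random(cm, 10, seed = 42)
  b <- select_random(cm, 10, seed = 42)
  expect_identical(a$chosen, b$chosen)
  expect_equal(nrow(a$chosen), 10L)
  expect_true(all(paste(a$chosen[, 1], a$chosen[, 2]) %in%
                    paste(cm$contacts[, 1], cm$contacts[, 2])))
  expect_equal(select_random(cm, 30, seed = 1)$chosen, cm$contacts)
  c2 <- select_random(cm, 10, seed = 43)
  expect_false(identical(a$chosen, c2$chosen))
})

test_that("random selections disperse more than clustered ones on average", {
  cm <- two_cluster_map()
  n <- 8L
  om_clustered <- vapply(1:100, function(s)
    gauss_score(contact_map(cm$L, select_clustered(cm, n, seed = s)$chosen)),
    numeric(1))
  om_random <- vapply(1:100, function(s)
    gauss_score(contact_map(cm$L, select_random(cm, n, seed = s)$chosen)),
    numeric(1))
  expect_gt(mean(om_random), mean(om_clustered))
})

test_that("Gauss-optimized selection finds the dispersed optimum", {
  # n = 2 among three collinear contacts: the extreme pair wins
  cm <- contact_map(40, rbind(c(1, 10), c(1, 12), c(1, 30)))
  sel <- select_gauss_optimized(cm, 2, seed = 1)
  expect_equal(sel$chosen, rbind(c(i = 1L, j = 10L), c(1L, 30L)),
               ignore_attr = "dimnames")
  expect_equal(gauss_score(contact_map(40, sel$chosen)), 2, tolerance = 1e-6)
  # n = 1 gives a single contact with Omega 1
  s1 <- select_gauss_optimized(cm, 1, seed = 1)
  expect_equal(nrow(s1$chosen), 1L)
  expect_equal(gauss_score(contact_map(40, s1$chosen)), 1)
})

test_that("Gauss-optimized output is single-swap locally optimal", {
  for (seed in 1:5) {
    cm <- random_contact_map(50, 16, seed = 300 + seed)
    sel <- select_gauss_optimized(cm, 6, seed = seed)
    om <- omega_direct(sel$chosen)
    chosen_key <- paste(sel$chosen[, 1], sel$chosen[, 2])
    all_key <- paste(cm$contacts[, 1], cm$contacts[, 2])
    out <- cm$contacts[!all_key %in% chosen_key, , drop = FALSE]
    for (r in seq_len(nrow(sel$chosen))) {
      for (a in seq_len(nrow(out))) {
        swapped <- rbind(sel$chosen[-r, , drop = FALSE], out[a, ])
        expect_lte(omega_direct(swapped), om + 1e-9)
      }
    }
  }
})

test_that("selection schemes order mean Omega as gauss >= random >= clustered", {
  oms <- sapply(1:30, function(s) {
    cm <- generate_planted_cluster_map(L = 80, seed = 500 + s)
    n <- min(10L, nrow(cm$contacts))
    c(clustered = gauss_score(contact_map(cm$L, select_clustered(cm, n, seed = s)$chosen)),
      random = gauss_score(contact_map(cm$L, select_random(cm, n, seed = s)$chosen)),
      gauss = gauss_score(contact_map(cm$L, select_gauss_optimized(cm, n, seed = s)$chosen)))
  })
  m <- rowMeans(oms)
  expect_gt(m["gauss"], m["random"])
  expect_gt(m["random"], m["clustered"])
})

test_that("false-contact injection hits the requested error rate", {
  cm <- random_contact_map(60, 20, seed = 8)
  base <- select_random(cm, 10, seed = 1)
  same <- inject_false_contacts(cm, base, 0, seed = 2)
  expect_identical(same$chosen, base$chosen)
  inj <- inject_false_contacts(cm, base, 1/3, seed = 2)
  expect_equal(nrow(inj$false_set), 5L) # k = round((1/3)*10/(2/3)) = 5
  expect_equal(inj$lambda, 1/3)
  # false contacts never collide with native ones
  expect_false(any(paste(inj$false_set[, 1], inj$false_set[, 2]) %in%
                     paste(cm$contacts[, 1], cm$contacts[, 2])))
  expect_true(all(inj$false_set[, 2] - inj$false_set[, 1] >= 4))
  expect_error(inject_false_contacts(cm, base, 1, seed = 2), "\\[0, 1\\)")
})

test_that("injection reports the achieved lambda when rounding intervenes", {
  cm <- random_contact_map(60, 20, seed = 8)
  base <- select_random(cm, 8, seed = 1)
  inj <- inject_false_contacts(cm, base, 0.25, seed = 3)
  k <- round(0.25 * 8 / 0.75)
  expect_equal(inj$lambda, k / (8 + k))
})

test_that("selection tables round-trip with labels and metadata", {
  cm <- random_contact_map(60, 20, seed = 8)
  sel <- inject_false_contacts(cm, select_random(cm, 9, seed = 5), 0.25, seed = 6)
  lines <- write_selection_table(sel)
  back <- read_selection_table(lines, parent = cm)
  expect_equal(back$chosen, sel$chosen)
  expect_equal(back$true_set, sel$true_set)
  expect_equal(back$false_set, sel$false_set)
  expect_equal(back$scheme, sel$scheme)
  expect_equal(back$lambda, sel$lambda)
})
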