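test_that("assign_to_beads respects the distance cutoff", {
  beads <- rbind(b1 = c(0, 0), b2 = c(10, 0))
  # one cell exactly at a bead center
  a <- assign_to_beads(rbind(c(0, 0)), beads, cutoff = 5)
  expect_equal(a$members$distance[a$members$bead == "b1"], 0)
  # a cell just beyond the cutoff is not assigned
  a2 <- assign_to_beads(rbind(c(5 + 1e-9, 0)), beads, cutoff = 5)
  expect_false("b1" %in% a2$members$bead)
  # hand-computed single assignment
  a3 <- suppressMessages(assign_to_beads(rbind(c(4, 0)), beads, cutoff = 5))
  expect_identical(a3$members$bead, "b1")
  expect_equal(a3$members$distance, 4)
  expect_true(all(a3$members$distance <= a3$cutoff))
  expect_error(assign_to_beads(rbind(c(0, 0, 0)), beads, 5),
               class = "stmap_validation_error")
  expect_error(assign_to_beads(rbind(c(0, 0)), beads, 0),
               class = "stmap_validation_error")
})

test_that("a cell may serve several beads and beads may be empty", {
  beads <- rbind(b1 = c(0, 0), b2 = c(2, 0), b3 = c(50, 50))
  a <- suppressMessages(assign_to_beads(rbind(c(1, 0)), beads, cutoff = 1.5))
  expect_setequal(a$members$bead, c("b1", "b2"))
  recon <- reconstruct_bead_expression(a, matrix(c(3, 7), 1))
  expect_identical(attr(recon, "empty_beads"), "b3")
  expect_true(all(is.na(as.matrix(recon$expr)["b3", ])))
})

test_that("reconstruction weights follow the inverse-distance rule", {
  expect_equal(reconstruction_weights(2.7), 1)
  expect_equal(reconstruction_weights(c(1, 1)), c(0.5, 0.5))
  expect_equal(reconstruction_weights(c(1, 3)), c(0.75, 0.25))
  # zero distance takes the limit: all mass on the coincident cell(s)
  expect_equal(reconstruction_weights(c(0, 2)), c(1, 0))
  expect_equal(reconstruction_weights(c(0, 0, 5)), c(0.5, 0.5, 0))
  expect_error(reconstruction_weights(numeric(0)),
               class = "stmap_validation_error")
  set.seed(5)
  for (i in 1:25) {
    w <- reconstruction_weights(runif(sample(1:8, 1), 0.01, 20))
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("bead expression is the weighted average of member cells", {
  beads <- rbind(b1 = c(0, 0))
  cells <- rbind(c(1, 0), c(3, 0))
  expr <- rbind(c(0, 10), c(4, 10))
  a <- assign_to_beads(cells, beads, cutoff = 5)
  recon <- reconstruct_bead_expression(a, expr)
  expect_equal(unname(as.matrix(recon$expr)[1, ]), c(0.75 * 0 + 0.25 * 4, 10))
  # single member: exact copy
  a1 <- suppressMessages(assign_to_beads(rbind(c(1, 0)), beads, cutoff = 2))
  r1 <- reconstruct_bead_expression(a1, rbind(c(5, 6)))
  expect_equal(unname(as.matrix(r1$expr)[1, ]), c(5, 6))
})

test_that("reconstruction is a convex combination of member expression", {
  set.seed(14)
  beads <- cbind(runif(6, 0, 40), runif(6, 0, 40))
  rownames(beads) <- paste0("b", 1:6)
  cells <- cbind(runif(40, 0, 40), runif(40, 0, 40))
  expr <- matrix(rexp(40 * 5), 40, 5)
  a <- suppressMessages(assign_to_beads(cells, beads, cutoff = 12))
  recon <- as.matrix(reconstruct_bead_expression(a, expr)$expr)
  for (b in rownames(beads)) {
    mem <- a$members$cell[a$members$bead == b]
    if (length(mem) == 0) next
    lo <- apply(expr[mem, , drop = FALSE], 2, min)
    hi <- apply(expr[mem, , drop = FALSE], 2, max)
    expect_true(all(recon[b, ] >= lo - 1e-12 & recon[b, ] <= hi + 1e-12))
  }
})

test_that("predictions at bead centers reproduce the query expression", {
  set.seed(3)
  beads <- cbind(x = seq(0, 90, by = 10), y = rep(c(0, 50), 5))
  rownames(beads) <- paste0("b", 1:10)
  expr <- matrix(rpois(10 * 4, 6), 10, 4)
  a <- assign_to_beads(beads, beads, cutoff = 4)  # below inter-bead spacing
  recon <- reconstruct_bead_expression(a, expr)
  expect_equal(unname(as.matrix(recon$expr)), unname(expr))
  expect_equal(unname(recon$coords), unname(beads))
})

test_that("the membership table carries normalized weights per bead", {
  beads <- rbind(b1 = c(0, 0), b2 = c(10, 0))
  cells <- rbind(c(1, 0), c(3, 0), c(9, 0))
  a <- assign_to_beads(cells, beads, cutoff = 4)
  tab <- assignment_table(a)
  expect_named(tab, c("bead", "cell", "distance", "weight"))
  sums <- tapply(tab$weight, tab$bead, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(tab$weight[tab$bead == "b1"], c(0.75, 0.25))
})
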