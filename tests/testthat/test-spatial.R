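test_that("nearest distance on the 3-4-5 fixture", {
  f <- make_cells(0, 0, id = "a")
  t <- make_cells(c(3, 6), c(4, 8), id = c("b", "c"))
  nd <- nearest_distance(f, t)
  expect_equal(unname(nd$per_cell), 5)
  expect_equal(nd$mnd, 5)
  expect_error(nearest_distance(f, t[0, ]), "no reference cells")
})

test_that("self-matching excludes identical cell ids", {
  set.seed(21)
  cells <- make_cells(runif(40, 0, 100), runif(40, 0, 100))
  nd <- nearest_distance(cells, cells)
  expect_true(all(nd$per_cell > 0))
  expect_equal(unname(nd$per_cell),
               oracle_nn(cells$x_um, cells$y_um, cells$x_um, cells$y_um,
                         excl = seq_len(40)))
})

test_that("grid-accelerated nearest distances equal brute force", {
  for (s in 1:5) {
    set.seed(100 + s)
    nf <- sample(50:500, 1); nt <- sample(50:500, 1)
    f <- make_cells(runif(nf, 0, 3000), runif(nf, 0, 3000))
    t <- make_cells(runif(nt, 0, 3000), runif(nt, 0, 3000),
                    id = sprintf("t%04d", seq_len(nt)))
    g <- nearest_distance(f, t, method = "grid")
    b <- nearest_distance(f, t, method = "brute")
    expect_identical(g$per_cell, b$per_cell)
    expect_equal(unname(g$per_cell),
                 oracle_nn(f$x_um, f$y_um, t$x_um, t$y_um))
  }
})

test_that("nearest-distance monotonicity when the to-set grows", {
  set.seed(31)
  f <- make_cells(runif(100, 0, 500), runif(100, 0, 500))
  t1 <- make_cells(runif(50, 0, 500), runif(50, 0, 500),
                   id = sprintf("t%03d", 1:50))
  t2 <- rbind(t1, make_cells(runif(50, 0, 500), runif(50, 0, 500),
                             id = sprintf("t%03d", 51:100)))
  d1 <- nearest_distance(f, t1)$per_cell
  d2 <- nearest_distance(f, t2)$per_cell
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("contact rule arithmetic at the threshold", {
  # default radius 5 um each + slack 1 -> threshold 11 um
  r <- make_cells(0, 0, id = "r")
  near <- make_cells(10.5, 0, id = "p1")
  far <- make_cells(11.5, 0, id = "p2")
  expect_equal(unname(count_contacts(r, near, "A")$per_reference_cell[1, 1]),
               1L)
  expect_equal(unname(count_contacts(r, far, "A")$per_reference_cell[1, 1]),
               0L)
  expect_error(count_contacts(r, near, "A", slack = -1), "negative slack")
})

test_that("contact counts equal brute force and the exhaustive oracle", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 300
    ref <- make_cells(runif(n, 0, 1000), runif(n, 0, 1000),
                      area = runif(n, 30, 150))
    par <- make_cells(runif(n, 0, 1000), runif(n, 0, 1000),
                      id = sprintf("p%04d", 1:n),
                      area = runif(n, 30, 150))
    lab <- sample(c("A", "B"), n, TRUE)
    cg <- count_contacts(ref, par, lab)
    cb <- count_contacts(ref, par, lab, method = "brute")
    expect_identical(cg$per_reference_cell, cb$per_reference_cell)
    for (l in c("A", "B")) {
      sel <- lab == l
      expect_equal(unname(cg$per_reference_cell[, l]),
                   oracle_contacts(ref$x_um, ref$y_um,
                                   sqrt(ref$cell_area_um2 / pi),
                                   par$x_um[sel], par$y_um[sel],
                                   sqrt(par$cell_area_um2[sel] / pi), 1))
    }
  }
})

test_that("contact pairs are symmetric between the two directions", {
  set.seed(33)
  a <- make_cells(runif(150, 0, 800), runif(150, 0, 800),
                  id = sprintf("a%03d", 1:150), area = runif(150, 40, 120))
  b <- make_cells(runif(120, 0, 800), runif(120, 0, 800),
                  id = sprintf("b%03d", 1:120), area = runif(120, 40, 120))
  ab <- count_contacts(a, b, rep("x", nrow(b)))
  ba <- count_contacts(b, a, rep("x", nrow(a)))
  expect_equal(unname(ab$total_pairs), unname(ba$total_pairs))
})

test_that("contact fractions are proportions of reference cells", {
  set.seed(44)
  ref <- make_cells(runif(80, 0, 300), runif(80, 0, 300))
  par <- make_cells(runif(200, 0, 300), runif(200, 0, 300),
                    id = sprintf("p%03d", 1:200))
  cr <- count_contacts(ref, par, rep("T", 200))
  expect_equal(unname(cr$contact_fraction["T"]),
               mean(cr$per_reference_cell[, "T"] >= 1))
  expect_true(all(cr$contact_fraction >= 0 & cr$contact_fraction <= 1))
})
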