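test_that("any segment on a uniform raster is 100% that class", {
  ls <- uniform_landscape(n = 50, class = "pasture")
  p <- buffer_proportions(c(100, 100, 400, 700), ls)
  expect_equal(unname(p["pasture"]), 1)
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("cell-center proportions agree with a Monte-Carlo area oracle", {
  ls <- fine_landscape()
  set.seed(3)
  ext <- c(500, 4000)
  for (i in 1:12) {
    x1 <- runif(1, ext[1], ext[2]); y1 <- runif(1, ext[1], ext[2])
    ang <- runif(1, 0, 2 * pi); len <- runif(1, 0, 300)
    seg <- c(x1, y1, x1 + len * cos(ang), y1 + len * sin(ang))
    p <- buffer_proportions(seg, ls)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    oracle <- mc_buffer_oracle(seg, ls, n_points = 100000, seed = i)
    expect_lt(max(abs(p - oracle[names(p)])), 0.02)
  }
})

test_that("cell-center approximation error shrinks with finer cells", {
  # matched segments: the deviation from the area oracle at 10 m cells is
  # below 0.01 and below the deviation at 30 m cells
  ls10 <- fine_landscape()
  # same landscape, aggregated to coarse 30 m cells (majority of 3x3 blocks)
  agg <- matrix(0L, 150, 150)
  for (r in 1:150) for (cc in 1:150) {
    blk <- ls10$grid[(3 * r - 2):(3 * r), (3 * cc - 2):(3 * cc)]
    agg[r, cc] <- as.integer(names(which.max(table(blk))))
  }
  ls30 <- landscape_raster(agg, cell_size = 30, origin = ls10$origin,
                           class_table = ls10$class_table)
  set.seed(5)
  err10 <- err30 <- numeric(5)
  for (i in 1:5) {
    x1 <- runif(1, 500, 4000); y1 <- runif(1, 500, 4000)
    seg <- c(x1, y1, x1 + runif(1, -200, 200), y1 + runif(1, -200, 200))
    oracle <- mc_buffer_oracle(seg, ls10, n_points = 200000, seed = 100 + i)
    p10 <- buffer_proportions(seg, ls10)
    p30 <- buffer_proportions(seg, ls30)
    err10[i] <- max(abs(p10 - oracle[names(p10)]))
    err30[i] <- max(abs(p30 - oracle[names(p30)]))
    expect_lt(err10[i], 0.01)
  }
  expect_lt(mean(err10), mean(err30))
})

test_that("composition is invariant to whole-cell origin translation", {
  ls <- patchy_landscape()
  seg <- c(3000, 3000, 3210, 3140)
  p1 <- buffer_proportions(seg, ls)
  ls2 <- ls
  ls2$origin <- ls$origin + c(5 * ls$cell_size, -3 * ls$cell_size)
  seg2 <- seg + c(5, -3, 5, -3) * ls$cell_size
  p2 <- buffer_proportions(seg2, ls2)
  expect_equal(p1, p2)
})

test_that("a zero-length segment buffers to a disc", {
  ls <- patchy_landscape()
  p <- buffer_proportions(c(4500, 4500, 4500, 4500), ls)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  oracle <- mc_buffer_oracle(c(4500, 4500, 4500, 4500), ls, seed = 8)
  expect_lt(max(abs(p - oracle[names(p)])), 0.05)
})

test_that("a segment outside the raster extent raises an error", {
  ls <- uniform_landscape(n = 10)
  expect_error(buffer_proportions(c(1e6, 1e6, 1e6 + 10, 1e6), ls), "extent")
})

test_that("cardinal alternatives have the observed length and endpoints", {
  alt <- alternative_steps(0, 0, 100)
  expect_equal(alt$candidate, c("east", "west", "north", "south"))
  expect_equal(alt$x2, c(100, -100, 0, 0))
  expect_equal(alt$y2, c(0, 0, 100, -100))
  lens <- sqrt((alt$x2 - alt$x1)^2 + (alt$y2 - alt$y1)^2)
  expect_equal(lens, rep(100, 4))
  expect_error(alternative_steps(0, 0, 0), "length > 0")
})

test_that("all five candidates are identical on a uniform raster", {
  ls <- uniform_landscape(n = 200)
  st <- make_steps(d = c(50, 120))
  st$x1 <- st$y1 <- 3000
  st$x2 <- st$x1 + st$d_m
  st$y2 <- st$y1
  comps <- step_compositions(st, ls)
  expect_equal(nrow(comps), 2 * 5 * 1) # 2 steps x 5 candidates x 1 class
  expect_true(all(comps$proportion == 1))
  expect_true(all(comps$set_valid))
})

test_that("rare classes are pruned only when rare for every individual", {
  base <- c(forest = 0.3, pasture = 0.6, wetland = 0.1)
  mk <- function(id, wet) {
    p <- c(forest = 0.5 - wet, pasture = 0.5, wetland = wet)
    make_comps(setNames(list(p, p), paste0(id, c("_1", "_2"))),
               individual_id = id)
  }
  comps <- dplyr::bind_rows(mk("i1", 0.04), mk("i2", 0.07), mk("i3", 0.09))
  rc <- prune_rare_classes(comps)
  expect_false("wetland" %in% rc$retained)
  expect_setequal(rc$retained, c("forest", "pasture"))
  # one individual above threshold keeps the class for everyone
  comps2 <- dplyr::bind_rows(mk("i1", 0.04), mk("i2", 0.07), mk("i3", 0.12))
  rc2 <- prune_rare_classes(comps2)
  expect_true("wetland" %in% rc2$retained)
})

test_that("a class absent from the raster is dropped", {
  p <- c(forest = 0.4, pasture = 0.6, mosaic = 0)
  comps <- make_comps(list(s1 = p, s2 = p))
  rc <- prune_rare_classes(comps)
  expect_false("mosaic" %in% rc$retained)
})

test_that("pruning the baseline class is a configuration error", {
  p <- c(forest = 0.95, pasture = 0.05)
  comps <- make_comps(list(s1 = p, s2 = p))
  expect_error(prune_rare_classes(comps), "baseline")
})

test_that("raising the pruning threshold never un-drops a class", {
  set.seed(11)
  plist <- lapply(1:20, function(i) {
    p <- rgamma(4, shape = c(4, 1, 0.5, 8))
    setNames(p / sum(p), c("forest", "savanna", "wetland", "pasture"))
  })
  names(plist) <- paste0("s", 1:20)
  comps <- make_comps(plist)
  thresholds <- c(0.02, 0.05, 0.10, 0.20, 0.40)
  retained_sets <- lapply(thresholds, function(th)
    prune_rare_classes(comps, th)$retained)
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(retained_sets[[i + 1]] %in% retained_sets[[i]]))
  }
})

test_that("pruning renormalizes proportions onto the retained classes", {
  p <- c(forest = 0.5, pasture = 0.4, wetland = 0.1)
  comps <- make_comps(list(s1 = p))
  rc <- structure(list(retained = c("forest", "pasture"), baseline = "pasture"),
                  class = "retained_classes")
  out <- apply_class_pruning(comps, rc)
  expect_equal(sort(unique(out$class)), c("forest", "pasture"))
  expect_equal(sum(out$proportion), 1)
  expect_equal(out$proportion[out$class == "forest"], 0.5 / 0.9)
})

test_that("choice sets near the raster edge are marked invalid", {
  ls <- uniform_landscape(n = 30) # 900 m x 900 m
  # observed step heads west from near the east edge; the east alternative
  # lies mostly outside the raster, invalidating the whole choice set
  st <- make_steps(d = 400)
  st$x1 <- 870; st$y1 <- 450
  st$x2 <- 470; st$y2 <- 450
  comps <- step_compositions(st, ls)
  expect_true(all(!comps$set_valid))
})
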