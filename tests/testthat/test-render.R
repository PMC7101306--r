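# Renderer and decoder: geometry, determinism, round trips, ablation,
# mirror symmetry, file IO.

lay <- default_layout()
pal <- default_palette()
rul <- default_rules()

test_that("a rendered image is exactly the canvas size", {
  img <- render_tda(fixture_record(), rul, pal, lay)
  expect_identical(dim(img), c(494L, 871L, 3L))
})

test_that("rendering is byte-stable across calls", {
  r <- fixture_record()
  i1 <- render_tda(r, rul, pal, lay)
  i2 <- render_tda(r, rul, pal, lay)
  expect_identical(i1, i2)
})

test_that("an all-negative record renders only green blocks and background", {
  img <- render_tda(fixture_negative_record(), rul, pal, lay)
  dec <- decode_tda(img, lay, pal)
  jcats <- dec[startsWith(names(dec), "J_")]
  expect_true(all(jcats == "green"))
  # the non-block area is pure background
  px <- unclass(img)[1, 1, ]
  expect_identical(as.integer(px), as.integer(pal$background))
})

test_that("decode(render(r)) equals discretize(r) on random records", {
  recs <- random_records(60, seed = 21)
  for (r in recs) {
    img <- render_tda(r, rul, pal, lay)
    dec <- decode_tda(img, lay, pal)
    dis <- discretize_record(r, rul)
    expect_identical(dec[names(dis)], dis)
  }
})

test_that("decoding an all-background image is an unrecognized-colour error", {
  img <- array(255L, dim = c(494L, 871L, 3L))
  expect_error(decode_tda(img, lay, pal), "unrecognized colour")
})

test_that("decoding a wrong-size image is a dimension error", {
  img <- array(255L, dim = c(100L, 100L, 3L))
  expect_error(decode_tda(img, lay, pal), "871")
})

test_that("swapping left/right joints mirrors the cruciform colours", {
  r <- fixture_record()
  swapped <- r
  for (site in tda_sites()) {
    swapped$joints[[paste0("left_", site)]] <-
      r$joints[[paste0("right_", site)]]
    swapped$joints[[paste0("right_", site)]] <-
      r$joints[[paste0("left_", site)]]
  }
  dec_orig <- decode_tda(render_tda(r, rul, pal, lay), lay, pal)
  dec_swap <- decode_tda(render_tda(swapped, rul, pal, lay), lay, pal)
  for (site in tda_sites()) {
    for (ch in c("a", "b", "c", "d", "e")) {
      expect_identical(
        unname(dec_swap[paste("J", "left", site, ch, sep = "_")]),
        unname(dec_orig[paste("J", "right", site, ch, sep = "_")]))
    }
  }
  # and raw pixels: the cruciform region of the swapped render is the
  # horizontal mirror of the original (the layout mirrors exactly)
  i1 <- unclass(render_tda(r, rul, pal, lay))
  i2 <- unclass(render_tda(swapped, rul, pal, lay))
  top <- max(lay$blocks$y1[lay$blocks$kind == "joint"])
  expect_identical(i2[1:top, 871:1, ], i1[1:top, , ])
})

test_that("missing values follow the missing-value policy", {
  r <- fixture_record()
  r$crp <- NA_real_
  expect_error(render_tda(r, rul, pal, lay), "crp")
  expect_warning(img <- render_tda(r, rul, pal, lay,
                                   missing_policy = "grey"), "crp")
  dec <- decode_tda(img, lay, pal)
  expect_identical(unname(dec["crp"]), "missing")
})

test_that("tiff and png files are lossless and agree with each other", {
  img <- render_tda(fixture_record(), rul, pal, lay)
  ft <- withr::local_tempfile(fileext = ".tiff")
  fp <- withr::local_tempfile(fileext = ".png")
  write_image(img, ft)
  write_image(img, fp)
  back_t <- read_image(ft)
  back_p <- read_image(fp)
  expect_identical(unclass(back_t)[, , ], unclass(img)[, , ])
  expect_identical(unclass(back_p)[, , ], unclass(img)[, , ])
  expect_identical(decode_tda(back_t, lay, pal), decode_tda(back_p, lay, pal))
})

test_that("ablation variants partition the non-background content", {
  r <- fixture_record()
  full <- unclass(render_tda(r, rul, pal, lay))
  cru <- unclass(split_ablation(r, "cruciform_only", rul, pal, lay))
  cli <- unclass(split_ablation(r, "clinical_only", rul, pal, lay))
  bg <- as.integer(pal$background)
  nonbg <- function(img) {
    img[, , 1] != bg[1] | img[, , 2] != bg[2] | img[, , 3] != bg[3]
  }
  m_full <- nonbg(full); m_cru <- nonbg(cru); m_cli <- nonbg(cli)
  expect_false(any(m_cru & m_cli))
  expect_identical(m_cru | m_cli, m_full)
})

test_that("decoding a cruciform-only image errors on the clinical squares", {
  img <- split_ablation(fixture_record(), "cruciform_only", rul, pal, lay)
  expect_error(decode_tda(img, lay, pal), "unrecognized colour")
  # but a layout restricted to joint blocks decodes cleanly
  jlay <- lay
  jlay$blocks <- lay$blocks[lay$blocks$kind == "joint", ]
  dec <- decode_tda(img, jlay, pal)
  dis <- discretize_record(fixture_record(), rul)
  expect_identical(dec, dis[names(dec)])
})

test_that("downscaling preserves exact palette colours", {
  img <- render_tda(fixture_record(), rul, pal, lay)
  small <- downscale_tda(img, 40, 40)
  expect_identical(dim(unclass(small)), c(40L, 40L, 3L))
  cols <- unique(matrix(unclass(small), ncol = 3))
  pm <- do.call(rbind, unname(default_palette()))
  for (i in seq_len(nrow(cols))) {
    expect_true(any(colSums(abs(t(pm) - cols[i, ])) == 0))
  }
})
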