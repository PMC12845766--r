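# Independent oracle: enumerate sliding-window origins directly (start at
# 0, step s, clamp the final origin so the window stays inside) and count
# them, without using the closed-form grid equations.
enumerate_origins <- function(len, k, s) {
  pos <- 0L
  origins <- 0L
  while (pos + k < len) {
    pos <- pos + s
    origins <- c(origins, min(pos, len - k))
  }
  origins
}

test_that("grid counts match brute-force window enumeration", {
  for (k in c(3L, 5L, 8L, 13L)) {
    for (s in unique(c(1L, 2L, 3L, k - 1L, k))) {
      if (s < 1L) next
      for (h in seq(k, 64L, by = 3L)) {
        for (w in c(k, k + 7L, 64L)) {
          grid <- compute_patch_grid(h, w, ada_params(k = k, s = s))
          expect_identical(grid$ph, length(enumerate_origins(h, k, s)))
          expect_identical(grid$pl, length(enumerate_origins(w, k, s)))
          expect_identical(grid$n, grid$ph * grid$pl)
        }
      }
    }
  }
})

test_that("grid handles exact fits and rejects undersized inputs", {
  p <- ada_params(k = 128L, s = 64L)
  g <- compute_patch_grid(128L, 128L, p)
  expect_equal(c(g$ph, g$pl, g$n), c(1, 1, 1))
  g <- compute_patch_grid(256L, 256L, ada_params(k = 128L, s = 128L))
  expect_equal(c(g$ph, g$pl, g$n), c(2, 2, 4))
  g <- compute_patch_grid(250L, 250L, ada_params(k = 128L, s = 64L))
  expect_equal(c(g$ph, g$pl, g$n), c(3, 3, 9))
  expect_error(compute_patch_grid(100L, 130L, p), "smaller than")
})

test_that("extraction emits the full grid in row-major order with clamped
           final origins", {
  rec <- random_record("r", 250L, 250L, seed = 5)
  patches <- extract_patches(rec, ada_params(k = 128L, s = 64L))
  expect_length(patches, 9)
  origins <- t(vapply(patches, function(p) c(p$row0, p$col0), integer(2)))
  expect_equal(unique(origins[, 1]), c(0L, 64L, 122L))
  expect_equal(origins[1:3, 2], c(0L, 64L, 122L))  # row-major: cols vary first
  # every patch lies inside the image and counts its own foreground
  for (p in patches) {
    expect_true(p$row0 >= 0 && p$row0 <= 250 - 128)
    expect_equal(p$foreground_count, sum(p$mask))
    expect_identical(dim(p$image), c(128L, 128L, 3L))
  }

  # exact tiling partitions the mask: foreground counts are conserved
  rec2 <- random_record("t", 256L, 256L, seed = 6)
  tiles <- extract_patches(rec2, ada_params(k = 128L, s = 128L))
  expect_length(tiles, 4)
  expect_equal(sum(vapply(tiles, `[[`, integer(1), "foreground_count")),
               sum(rec2$mask))
  expect_equal(lapply(tiles, function(p) c(p$row0, p$col0)),
               list(c(0L, 0L), c(0L, 128L), c(128L, 0L), c(128L, 128L)))
})

test_that("undersized images are mirror-padded up to the patch size", {
  rec <- square_record(h = 100L, w = 140L, top = 5L, left = 5L, side = 4L)
  expect_message(patches <- extract_patches(rec, ada_params(k = 128L, s = 64L)),
                 "mirror-padding")
  expect_identical(dim(patches[[1]]$mask), c(128L, 128L))
})

test_that("balance filter keeps strictly-above-threshold patches in order", {
  mk <- function(fg) {
    m <- matrix(0L, 16, 16); if (fg > 0) m[seq_len(fg)] <- 1L
    maunet:::new_patch(array(0, c(16, 16, 3)), m, "x", 0L, 0L)
  }
  fl <- filter_patches(lapply(c(0L, 9L, 10L, 200L), mk), 9L)
  expect_equal(vapply(fl$kept, `[[`, integer(1), "foreground_count"),
               c(10L, 200L))  # 9 is discarded: strict inequality
  expect_equal(fl$alpha, 2L)
  expect_equal(fl$n_alpha, 2L)

  all_bg <- filter_patches(lapply(rep(0L, 9), mk), 9L)
  expect_length(all_bg$kept, 0)
  expect_equal(all_bg$alpha, 9L)
  expect_equal(all_bg$n_alpha, 0L)
})

test_that("alpha accounting and foreground enrichment hold over random
           images", {
  params <- ada_params(k = 16L, s = 8L, alpha_threshold = 5L)
  means_all <- c(); means_kept <- c()
  for (i in 1:100) {
    h <- 16L + (i %% 5L) * 7L
    w <- 16L + (i %% 3L) * 11L
    rec <- random_record(paste0("p", i), h, w, p_fg = 0.03, seed = i)
    patches <- extract_patches(rec, params)
    grid <- compute_patch_grid(h, w, params)
    fl <- filter_patches(patches, params$alpha_threshold)
    expect_identical(fl$alpha + fl$n_alpha, grid$n)
    counts <- vapply(patches, `[[`, integer(1), "foreground_count")
    means_all <- c(means_all, mean(counts))
    if (fl$n_alpha > 0)
      means_kept <- c(means_kept,
                      mean(vapply(fl$kept, `[[`, integer(1),
                                  "foreground_count")))
  }
  expect_true(mean(means_kept) >= mean(means_all))
})

test_that("geometric augmentations are involutive and mask-preserving", {
  rec <- random_record("a", 64L, 64L, p_fg = 0.2, seed = 9)
  patch <- extract_patches(rec, ada_params(k = 64L, s = 64L))[[1]]
  # flip twice restores the patch
  expect_identical(flip_patch(flip_patch(patch, "horizontal"), "horizontal"),
                   patch)
  expect_identical(flip_patch(flip_patch(patch, "vertical"), "vertical"),
                   patch)
  # four quarter-turns restore the patch
  expect_equal(rotate_patch(rotate_patch(patch, 2), 2)$image, patch$image)
  # any geometric op permutes pixels: foreground count invariant
  for (q in 1:3)
    expect_equal(sum(rotate_patch(patch, q)$mask), sum(patch$mask))
  # blur touches the image only
  blurred <- blur_patch(patch, sigma = 1.2)
  expect_identical(blurred$mask, patch$mask)
  expect_false(identical(blurred$image, patch$image))
  # the random pipeline never changes the mask's foreground count and is
  # reproducible per seed
  for (seed in 1:10) {
    aug <- augment_patch(patch, seed)
    expect_equal(sum(aug$mask), sum(patch$mask))
    expect_true(all(aug$mask %in% c(0L, 1L)))
    expect_identical(aug, augment_patch(patch, seed))
  }
})

test_that("patch preparation aggregates, augments and reports per image", {
  r1 <- random_record("im1", 256L, 256L, p_fg = 0.2, seed = 11)
  r2 <- square_record("im2", 256L, 256L, side = 2L)  # 4 fg px only
  r3 <- random_record("im3", 256L, 256L, p_fg = 0.2, seed = 12)
  params <- ada_params(k = 128L, s = 128L, alpha_threshold = 0L,
                       aug_fraction = 0)
  pd <- prepare_patch_dataset(manual_split(list(r1, r3), list(r1), list(r3)),
                              params)
  expect_length(pd$train, 8)  # 4 per image, nothing filtered or augmented
  expect_equal(sum(pd$report$N_alpha[pd$report$subset == "train"]), 8)

  # threshold 9 silences the nearly-empty image
  params9 <- ada_params(k = 128L, s = 128L, alpha_threshold = 9L,
                        aug_fraction = 0)
  pd9 <- prepare_patch_dataset(manual_split(list(r1, r2), list(r1), list(r3)),
                               params9)
  expect_length(pd9$train, 4)
  rep2 <- pd9$report[pd9$report$id == "im2", ]
  expect_equal(rep2$alpha, 4)
  expect_equal(rep2$N_alpha, 0)

  # augmentation appends; the report still counts pre-augmentation patches
  paug <- ada_params(k = 128L, s = 128L, alpha_threshold = 0L,
                     aug_fraction = 0.5, seed = 21L)
  pdaug <- prepare_patch_dataset(manual_split(list(r1, r3), list(r1),
                                              list(r3)), paug)
  expect_length(pdaug$train, 12)  # 8 kept + 4 augmented copies
  expect_equal(sum(pdaug$report$N_alpha[pdaug$report$subset == "train"]), 8)

  # determinism: identical seed, byte-identical ensembles
  pdaug2 <- prepare_patch_dataset(manual_split(list(r1, r3), list(r1),
                                               list(r3)), paug)
  expect_identical(pdaug$train, pdaug2$train)
})

test_that("patch ensembles survive a disk round-trip", {
  rec <- random_record("rt", 256L, 256L, p_fg = 0.1, seed = 31)
  patches <- extract_patches(rec, ada_params(k = 128L, s = 128L))
  dir <- withr::local_tempdir()
  save_patches(patches, dir)
  back <- load_patches(dir)
  expect_length(back, length(patches))
  key <- function(ps) lapply(ps, function(p) list(p$source_id, p$row0,
                                                  p$col0, p$mask))
  expect_identical(key(back)[order(vapply(back, `[[`, 0L, "row0"),
                                   vapply(back, `[[`, 0L, "col0"))],
                   key(patches)[order(vapply(patches, `[[`, 0L, "row0"),
                                      vapply(patches, `[[`, 0L, "col0"))])
})
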