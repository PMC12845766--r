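# Shared fixture builders. Everything is generated in code; no binary
# fixtures live on disk.

# A deterministic record with a hand-placed square nucleus, convenient when
# a test needs exact foreground counts.
square_record <- function(id = "sq", h = 128L, w = 128L,
                          top = 10L, left = 20L, side = 8L,
                          level = 200) {
  mask <- matrix(0L, h, w)
  mask[top + seq_len(side) - 1L, left + seq_len(side) - 1L] <- 1L
  img <- array(30, c(h, w, 3))
  for (ch in 1:3) img[, , ch][mask == 1L] <- level
  image_record(id, img, mask)
}

# Random-mask record for property checks (not meant to look like
# microscopy).
random_record <- function(id, h, w, p_fg = 0.1, seed = 1) {
  mask <- maunet:::with_seed(seed, matrix(rbinom(h * w, 1L, p_fg), h, w))
  img <- maunet:::with_seed(seed + 1L, array(runif(h * w * 3, 0, 255),
                                             c(h, w, 3)))
  image_record(id, img, mask)
}

# Minimal dataset_split wrapper for patch-stage tests.
manual_split <- function(train, validation = list(), test = list()) {
  structure(list(train = train, validation = validation, test = test,
                 seed = 0L), class = "dataset_split")
}

# Small, easily learnable patch set at 64 px (the network accepts any size
# divisible by 64).
tiny_patch_set <- function(n = 4L, seed = 3L) {
  recs <- lapply(seq_len(n), function(i)
    generate_sample(synth_config(height = 64L, width = 64L, n_nuclei = 3L,
                                 radius_range = c(4, 8), seed = seed + i)))
  unlist(lapply(recs, function(r)
    extract_patches(r, ada_params(k = 64L, s = 64L))), recursive = FALSE)
}
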