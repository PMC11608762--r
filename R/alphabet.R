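# Alphabet SCM: a 256x256 realization is an 8x8 grid of 32x32-pixel letter
# tiles drawn from A = {H, K, L, V, W, X, Y, Z}. Every realization contains
# the exact letter multiset
#   B = {24 H, 2 K, 16 L, 1 V, 1 W, 8 X, 8 Y, 4 Z}
# and the paired letters occur only inside their prescribed ordered pairs:
# X-Y horizontally (Y immediately right of X) and Z above each of K, V, W.
# Per-image pair prevalences are therefore 8 (X-Y), 2 (Z-K), 1 (Z-V), 1 (Z-W).

ALPHABET_LETTERS <- c("H", "K", "L", "V", "W", "X", "Y", "Z")

#' Prescribed per-image letter multiset of the alphabet model
#' @return named integer vector of per-image letter counts (sums to 64).
#' @export
alphabet_multiset <- function() {
  c(H = 24L, K = 2L, L = 16L, V = 1L, W = 1L, X = 8L, Y = 8L, Z = 4L)
}

# 8x8 block-letter masks, upscaled x4 to 32x32. "#" = foreground.
.glyph_rows <- list(
  H = c("##....##", "##....##", "##....##", "########",
        "########", "##....##", "##....##", "##....##"),
  K = c("##...###", "##..##..", "##.##...", "####....",
        "####....", "##.##...", "##..##..", "##...###"),
  L = c("##......", "##......", "##......", "##......",
        "##......", "##......", "########", "########"),
  V = c("##....##", "##....##", "##....##", "##....##",
        ".##..##.", ".##..##.", "..####..", "...##..."),
  W = c("##....##", "##....##", "##....##", "##.##.##",
        "##.##.##", "########", "###..###", "##....##"),
  X = c("##....##", ".##..##.", "..####..", "...##...",
        "...##...", "..####..", ".##..##.", "##....##"),
  Y = c("##....##", ".##..##.", "..####..", "...##...",
        "...##...", "...##...", "...##...", "...##..."),
  Z = c("########", "########", ".....##.", "....##..",
        "..###...", ".##.....", "########", "########")
)

#' Glyph bitmaps for the alphabet model
#'
#' Deterministic block-style 32x32 binary bitmaps (foreground 255,
#' background 0) for the eight letters. The bitmaps are versioned fixtures:
#' the same set is always returned, and all 28 distinct pairs have normalized
#' cross-correlation below 0.8 so that template matching is unambiguous.
#'
#' @return named list of eight 32x32 integer matrices.
#' @export
build_glyph_set <- function() {
  lapply(.glyph_rows, function(rows) {
    bits <- t(sapply(rows, function(r) as.integer(strsplit(r, "")[[1]] == "#")))
    g <- kronecker(bits, matrix(1L, 4, 4)) * 255L
    storage.mode(g) <- "integer"
    dimnames(g) <- NULL
    g
  })
}

#' Normalized cross-correlation between two tiles
#'
#' Pearson correlation of the flattened pixel vectors; 1 for identical tiles.
#' Returns 0 when either tile is constant (correlation undefined).
#'
#' @param a,b numeric matrices of equal size.
#' @return scalar in `[-1, 1]`.
#' @export
ncc_score <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  if (sd(av) == 0 || sd(bv) == 0) return(0)
  cor(av, bv)
}

# The 12 pair "dominoes": 8 horizontal X-Y, and Z above K (x2), V, W.
.alphabet_dominoes <- function() {
  c(rep("XY", 8), rep("ZK", 2), "ZV", "ZW")
}

#' Sample a constraint-exact letter layout
#'
#' Places the 12 letter-pair dominoes (8 horizontal X-Y; Z stacked above each
#' K, V and W) at uniformly random admissible grid positions in random order,
#' restarting from scratch whenever a domino has no admissible slot, then
#' fills the 40 remaining cells with a random permutation of 24 H and 16 L.
#' The multiset and pair constraints hold by construction.
#'
#' @param seed integer seed; distinct seeds give independent layouts.
#' @param max_restarts cap on placement restarts before failing.
#' @return `letter_layout` object: an 8x8 character matrix with a `seed`
#'   attribute.
#' @export
sample_letter_layout <- function(seed, max_restarts = 10000) {
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      grid <- matrix(NA_character_, 8, 8)
      ok <- TRUE
      for (dom in sample(.alphabet_dominoes())) {
        free <- is.na(grid)
        if (dom == "XY") {        # cells (r, c) and (r, c + 1)
          slots <- which(free[, 1:7] & free[, 2:8], arr.ind = TRUE)
        } else {                  # Z at (r, c), partner at (r + 1, c)
          slots <- which(free[1:7, ] & free[2:8, ], arr.ind = TRUE)
        }
        if (nrow(slots) == 0) { ok <- FALSE; break }
        s <- slots[sample.int(nrow(slots), 1), ]
        if (dom == "XY") {
          grid[s[1], s[2]] <- "X"; grid[s[1], s[2] + 1] <- "Y"
        } else {
          grid[s[1], s[2]] <- "Z"; grid[s[1] + 1, s[2]] <- substr(dom, 2, 2)
        }
      }
      if (ok) {
        fill <- sample(c(rep("H", 24), rep("L", 16)))
        grid[is.na(grid)] <- fill
        attr(grid, "seed") <- as.integer(seed)
        class(grid) <- c("letter_layout", class(grid))
        return(grid)
      }
    }
    stop("layout sampling exhausted restart budget", call. = FALSE)
  })
}

#' Render an alphabet realization from a layout
#'
#' Stamps the 32x32 glyph bitmap of each grid letter into its tile, producing
#' a 256x256 8-bit image with tile boundaries at multiples of 32.
#'
#' @param layout 8x8 character matrix of letters.
#' @param glyphs glyph set from [build_glyph_set()].
#' @return 256x256 integer matrix.
#' @export
render_realization <- function(layout, glyphs = build_glyph_set()) {
  stopifnot(all(dim(layout) == c(8, 8)), all(layout %in% names(glyphs)))
  img <- matrix(0L, 256, 256)
  for (r in 1:8) for (c in 1:8) {
    img[(r - 1) * 32 + 1:32, (c - 1) * 32 + 1:32] <- glyphs[[layout[r, c]]]
  }
  img
}

#' Recover a letter layout by template matching
#'
#' Assigns each 32x32 tile the glyph with the highest normalized
#' cross-correlation score. A realization is `recognizable` only when all 64
#' best scores reach `threshold`; per-tile scores are returned for audit.
#'
#' @param image 256x256 numeric matrix.
#' @param glyphs glyph set from [build_glyph_set()].
#' @param threshold minimum acceptable best match score in `[0, 1]`.
#' @return list with `layout` (8x8 character matrix), `scores` (8x8 numeric
#'   matrix of best scores) and `recognizable` (logical).
#' @export
recover_layout <- function(image, glyphs = build_glyph_set(), threshold = 0.9) {
  assert_image(image, c(256, 256))
  layout <- matrix(NA_character_, 8, 8)
  scores <- matrix(NA_real_, 8, 8)
  for (r in 1:8) for (c in 1:8) {
    tile <- image[(r - 1) * 32 + 1:32, (c - 1) * 32 + 1:32]
    sc <- vapply(glyphs, function(g) ncc_score(tile, g), numeric(1))
    best <- which.max(sc)
    layout[r, c] <- names(glyphs)[best]
    scores[r, c] <- sc[best]
  }
  list(layout = layout, scores = scores,
       recognizable = all(scores >= threshold))
}

#' Chi-squared goodness of fit for per-image letter prevalence
#'
#' Tests observed per-letter counts against the prescribed multiset using the
#' chi-squared statistic with 7 degrees of freedom; a realization passes when
#' the statistic does not exceed the 95th-percentile critical value.
#'
#' @param counts named per-letter counts summing to 64 (names as in the
#'   alphabet; missing letters count 0).
#' @param critical_p critical quantile of the null chi-squared distribution.
#' @return list with `chi2`, `critical`, `pass`, and `exact` (counts equal the
#'   multiset exactly).
#' @export
letter_prevalence_gof <- function(counts, critical_p = 0.95) {
  expected <- alphabet_multiset()
  obs <- setNames(rep(0L, 8), names(expected))
  obs[names(counts)] <- as.integer(counts)
  if (sum(obs) != 64) stop("letter counts must sum to 64", call. = FALSE)
  chi2 <- sum((obs - expected)^2 / expected)
  crit <- qchisq(critical_p, df = length(expected) - 1)
  list(chi2 = chi2, critical = crit, pass = chi2 <= crit,
       exact = all(obs == expected))
}

#' Letter-pair prevalence and orphan audit
#'
#' Scans all horizontal and vertical adjacencies of a (not necessarily
#' constraint-satisfying) 8x8 letter grid, counting the ordered pairs X-Y
#' (Y right of X), Z-K, Z-V and Z-W (Z above the partner), and flagging every
#' paired letter that does not sit inside its prescribed pairing.
#'
#' @param layout 8x8 character matrix.
#' @return list with `counts` (named integer vector for XY, ZK, ZV, ZW),
#'   `orphans` (two-column matrix of grid positions of orphaned letters),
#'   `n_orphans`, and `ok` (counts are 8, 2, 1, 1 with no orphans).
#' @export
pair_prevalence <- function(layout) {
  stopifnot(all(dim(layout) == c(8, 8)))
  right <- cbind(layout[, -1], NA)
  below <- rbind(layout[-1, ], NA)
  above <- rbind(NA, layout[-8, ])
  left  <- cbind(NA, layout[, -8])
  counts <- c(
    XY = sum(layout == "X" & right == "Y", na.rm = TRUE),
    ZK = sum(layout == "Z" & below == "K", na.rm = TRUE),
    ZV = sum(layout == "Z" & below == "V", na.rm = TRUE),
    ZW = sum(layout == "Z" & below == "W", na.rm = TRUE)
  )
  orphan <- (layout == "X" & (is.na(right) | right != "Y")) |
    (layout == "Y" & (is.na(left) | left != "X")) |
    (layout %in% c("K", "V", "W") & (is.na(above) | above != "Z")) |
    (layout == "Z" & (is.na(below) | !below %in% c("K", "V", "W")))
  list(counts = counts,
       orphans = which(orphan, arr.ind = TRUE),
       n_orphans = sum(orphan),
       ok = all(counts == c(8L, 2L, 1L, 1L)) && !any(orphan))
}

#' Generate an ensemble of alphabet realizations
#'
#' Per-image seeds are derived as `seed + index`, so ensembles are
#' reproducible image by image.
#'
#' @param n ensemble size.
#' @param seed ensemble seed.
#' @return list with `images`, `layouts` and a `manifest` data frame
#'   (filename, model, seed, layout hash).
#' @export
generate_alphabet_ensemble <- function(n, seed) {
  glyphs <- build_glyph_set()
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  layouts <- lapply(seeds, sample_letter_layout)
  images <- lapply(layouts, render_realization, glyphs = glyphs)
  manifest <- data.frame(
    filename = sprintf("alphabet_%05d.png", seq_len(n)),
    model = "alphabet",
    seed = seeds,
    layout_hash = vapply(layouts, function(l) paste(l, collapse = ""),
                         character(1)),
    stringsAsFactors = FALSE
  )
  list(images = images, layouts = layouts, manifest = manifest)
}
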