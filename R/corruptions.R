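# Error-mode injectors. Each corruption affects exactly round(rate * n)
# images (sampled without replacement), injects exactly one violation of the
# named kind per affected image, and records ground truth in a manifest, so
# detector recall and precision are unambiguous.

.pick_affected <- function(n, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  n_aff <- round(rate * n)
  if (n_aff == 0) return(integer(0))
  with_seed(derive_seed(seed, 0), sort(sample.int(n, n_aff)))
}

.truth_frame <- function(manifest, mode, affected) {
  data.frame(filename = manifest$filename, mode = mode,
             affected = seq_len(nrow(manifest)) %in% affected,
             stringsAsFactors = FALSE)
}

# Corrupt one alphabet layout in place; returns the modified layout or NULL
# when the mode has no eligible site (caller resamples the image).
.corrupt_one_layout <- function(layout, mode) {
  lay <- matrix(as.character(layout), 8, 8)
  if (mode == "swap_pair_order") {
    xs <- which(lay == "X", arr.ind = TRUE)
    s <- xs[sample.int(nrow(xs), 1), ]
    lay[s[1], s[2]] <- "Y"; lay[s[1], s[2] + 1] <- "X"
  } else if (mode == "duplicate_pair") {
    # overwrite a vertical filler pair with an extra Z-K
    free <- matrix(lay %in% c("H", "L"), 8, 8)
    slots <- which(free[1:7, ] & free[2:8, ], arr.ind = TRUE)
    if (nrow(slots) == 0) return(NULL)
    s <- slots[sample.int(nrow(slots), 1), ]
    lay[s[1], s[2]] <- "Z"; lay[s[1] + 1, s[2]] <- "K"
  } else if (mode == "orphan_letter") {
    fill <- which(lay == "H")
    if (length(fill) == 0) return(NULL)
    lay[fill[sample.int(length(fill), 1)]] <- "X"
  } else if (mode == "replace_letter") {
    fill <- which(lay == "H")
    if (length(fill) == 0) return(NULL)
    lay[fill[sample.int(length(fill), 1)]] <- "L"
  } else stop("unknown alphabet corruption mode: ", mode, call. = FALSE)
  lay
}

#' Corrupt an alphabet ensemble
#'
#' Modes: `swap_pair_order` reverses one X-Y pair to Y-X (two orphans, X-Y
#' count 7); `duplicate_pair` adds an extra Z-K pair over filler letters (Z-K
#' count 3); `orphan_letter` turns one filler H into a lone X;
#' `replace_letter` swaps one filler H for an L, breaking exact letter
#' prevalence while leaving all pairings intact.
#'
#' @param ensemble result of [generate_alphabet_ensemble()].
#' @param mode corruption mode.
#' @param rate fraction of images affected.
#' @param seed integer seed.
#' @return the ensemble with corrupted `layouts`/`images` plus a `truth`
#'   data frame.
#' @export
corrupt_alphabet <- function(ensemble, mode, rate, seed) {
  mode <- match.arg(mode, c("swap_pair_order", "duplicate_pair",
                            "orphan_letter", "replace_letter"))
  affected <- .pick_affected(length(ensemble$images), rate, seed)
  glyphs <- build_glyph_set()
  for (i in affected) {
    lay <- with_seed(derive_seed(seed, i),
                     .corrupt_one_layout(ensemble$layouts[[i]], mode))
    if (is.null(lay)) {   # no eligible site: resample the image, then corrupt
      ensemble$layouts[[i]] <- sample_letter_layout(derive_seed(seed, i + 10000L))
      lay <- with_seed(derive_seed(seed, i),
                       .corrupt_one_layout(ensemble$layouts[[i]], mode))
    }
    ensemble$layouts[[i]] <- lay
    ensemble$images[[i]] <- render_realization(lay, glyphs)
  }
  ensemble$truth <- .truth_frame(ensemble$manifest, mode, affected)
  ensemble
}

#' Corrupt a Voronoi ensemble
#'
#' Modes: `permute_intensities` randomly permutes the region gray levels
#' (destroying the area-gray rank correlation); `erase_edge_segment` fills the
#' edge pixels inside a 16-pixel disc with an adjacent region's intensity
#' (locally merging two regions); `off_class_count` regenerates the image with
#' a region count outside the class set (40 or 80, chosen at random).
#'
#' @param ensemble result of [generate_voronoi_ensemble()].
#' @param mode corruption mode.
#' @param rate fraction of images affected.
#' @param seed integer seed.
#' @return the ensemble with corrupted entries plus a `truth` data frame.
#' @export
corrupt_voronoi <- function(ensemble, mode, rate, seed) {
  mode <- match.arg(mode, c("permute_intensities", "erase_edge_segment",
                            "off_class_count"))
  affected <- .pick_affected(length(ensemble$images), rate, seed)
  for (i in affected) {
    re <- ensemble$realizations[[i]]
    s <- derive_seed(seed, i)
    if (mode == "permute_intensities") {
      re <- with_seed(s, {
        perm <- sample(nrow(re$regions))
        re$regions$gray <- re$regions$gray[perm]
        img <- matrix(0L, nrow(re$image), ncol(re$image))
        pos <- re$label_map > 0
        img[pos] <- re$regions$gray[re$label_map[pos]]
        re$image <- img
        re
      })
    } else if (mode == "erase_edge_segment") {
      re <- with_seed(s, {
        ed <- which(re$edge_mask &
                      row(re$edge_mask) > 8 & row(re$edge_mask) < 249 &
                      col(re$edge_mask) > 8 & col(re$edge_mask) < 249)
        site <- arrayInd(ed[sample.int(length(ed), 1)], dim(re$edge_mask))
        rr <- row(re$image) - site[1]; cc <- col(re$image) - site[2]
        disc <- rr^2 + cc^2 <= 16^2
        patch <- disc & re$edge_mask
        # fill with the gray of the dominant neighboring region in the disc
        nb_labels <- re$label_map[disc & re$label_map > 0]
        fill <- re$regions$gray[modal_label(nb_labels)]
        re$image[patch] <- fill
        re
      })
    } else {
      n_off <- with_seed(s, sample(c(40L, 80L), 1))
      re <- generate_voronoi(n_off, s)
    }
    ensemble$realizations[[i]] <- re
    ensemble$images[[i]] <- re$image
  }
  ensemble$truth <- .truth_frame(ensemble$manifest, mode, affected)
  ensemble
}

# most frequent positive label
modal_label <- function(x) {
  tb <- tabulate(x)
  which.max(tb)
}

#' Corrupt a flag ensemble
#'
#' Modes: `misplace_tile` swaps one foreground tile with one (non-forbidden)
#' background tile and redraws both (RMAE reports 2 error tiles, class
#' unchanged); `forbidden_fg_tile` moves one foreground tile onto a
#' never-foreground index (conserving the 80-count and triggering the
#' forbidden-violation flag); `wrong_intensity_law` redraws all foreground
#' pixels with the background Beta shape (2, 4) transplanted onto the
#' foreground support `[96, 248]`, so tile means stay above the
#' foreground/background decision threshold and only the intensity law is
#' violated.
#'
#' @param ensemble result of [generate_flag_ensemble()].
#' @param mode corruption mode.
#' @param rate fraction of images affected.
#' @param seed integer seed.
#' @return the ensemble with corrupted entries plus a `truth` data frame.
#' @export
corrupt_flags <- function(ensemble, mode, rate, seed) {
  mode <- match.arg(mode, c("misplace_tile", "forbidden_fg_tile",
                            "wrong_intensity_law"))
  affected <- .pick_affected(length(ensemble$images), rate, seed)
  templates <- ensemble$templates
  forb <- forbidden_tiles(templates)
  redraw_tile <- function(img, k, fg) {
    r <- (k - 1L) %% FLAG_GRID
    c <- (k - 1L) %/% FLAG_GRID
    img[r * FLAG_TILE + 1:16, c * FLAG_TILE + 1:16] <- sample_tile(fg)
    img
  }
  for (i in affected) {
    re <- ensemble$realizations[[i]]
    ensemble$realizations[[i]] <- with_seed(derive_seed(seed, i), {
      pat <- re$pattern
      if (mode == "misplace_tile") {
        fg <- which(pat == 1L)
        bg <- setdiff(which(pat == 0L), forb)
        k1 <- fg[sample.int(length(fg), 1)]
        k2 <- bg[sample.int(length(bg), 1)]
        pat[k1] <- 0L; pat[k2] <- 1L
        re$image <- redraw_tile(re$image, k1, FALSE)
        re$image <- redraw_tile(re$image, k2, TRUE)
      } else if (mode == "forbidden_fg_tile") {
        fg <- which(pat == 1L)
        k1 <- fg[sample.int(length(fg), 1)]
        k2 <- forb[sample.int(length(forb), 1)]
        pat[k1] <- 0L; pat[k2] <- 1L
        re$image <- redraw_tile(re$image, k1, FALSE)
        re$image <- redraw_tile(re$image, k2, TRUE)
      } else {
        for (k in which(pat == 1L)) {
          r <- (k - 1L) %% FLAG_GRID
          c <- (k - 1L) %/% FLAG_GRID
          v <- round(152 * rbeta(FLAG_TILE^2, 2, 4) + 96)
          re$image[r * FLAG_TILE + 1:16, c * FLAG_TILE + 1:16] <-
            matrix(as.integer(v), FLAG_TILE, FLAG_TILE)
        }
      }
      re$pattern <- pat
      re
    })
    ensemble$images[[i]] <- ensemble$realizations[[i]]$image
  }
  ensemble$truth <- .truth_frame(ensemble$manifest, mode, affected)
  ensemble
}

#' Corrupt a phantom ensemble
#'
#' Delegates to [break_ligaments()]; listed here so every model has a
#' corruption entry point.
#'
#' @inheritParams break_ligaments
#' @param mode only `"break_ligament"` is defined.
#' @param rate fraction of images affected.
#' @export
corrupt_phantom <- function(ensemble, mode = "break_ligament", rate, seed) {
  mode <- match.arg(mode, "break_ligament")
  out <- break_ligaments(ensemble, rate, seed)
  out$truth <- data.frame(filename = out$manifest$filename, mode = mode,
                          affected = out$manifest$broken,
                          stringsAsFactors = FALSE)
  out
}
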