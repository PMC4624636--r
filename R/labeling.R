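# 8-connected component labeling for binary matrices.
#
# EBImage::bwlabel is 4-connected; diagonal-only contacts are merged
# afterwards with a union-find pass over the two diagonal neighbor offsets,
# which yields exact 8-connectivity at vectorized cost.

label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs: (i,j)-(i+1,j+1) and (i+1,j)-(i,j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) union_(pairs[r, 1], pairs[r, 2])
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Zhang-Suen morphological thinning of a binary matrix (small inputs).
zhang_suen_thin <- function(mask) {
  img <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  img[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  changed <- TRUE
  neighbors <- function(img) {
    nr <- nrow(img); nc <- ncol(img)
    core <- 2:(nr - 1)
    corc <- 2:(nc - 1)
    list(p2 = img[core - 1, corc, drop = FALSE], p3 = img[core - 1, corc + 1, drop = FALSE],
         p4 = img[core, corc + 1, drop = FALSE], p5 = img[core + 1, corc + 1, drop = FALSE],
         p6 = img[core + 1, corc, drop = FALSE], p7 = img[core + 1, corc - 1, drop = FALSE],
         p8 = img[core, corc - 1, drop = FALSE], p9 = img[core - 1, corc - 1, drop = FALSE])
  }
  while (changed) {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbors(img)
      P <- img[2:(nrow(img) - 1), 2:(ncol(img) - 1), drop = FALSE]
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- Reduce(`+`, lapply(1:8, function(i) (seqs[[i]] == 0) & (seqs[[i + 1]] == 1)))
      if (step == 1) {
        cond <- P == 1 & B >= 2 & B <= 6 & A == 1 &
          (nb$p2 * nb$p4 * nb$p6 == 0) & (nb$p4 * nb$p6 * nb$p8 == 0)
      } else {
        cond <- P == 1 & B >= 2 & B <= 6 & A == 1 &
          (nb$p2 * nb$p4 * nb$p8 == 0) & (nb$p2 * nb$p6 * nb$p8 == 0)
      }
      if (any(cond)) {
        P[cond] <- 0L
        img[2:(nrow(img) - 1), 2:(ncol(img) - 1)] <- P
        changed <- TRUE
      }
    }
  }
  img[2:(nrow(img) - 1), 2:(ncol(img) - 1), drop = FALSE] == 1L
}

# chain length of a skeleton mask: orthogonal links + sqrt(2) diagonal links,
# diagonal links only counted when not shortcut by an orthogonal pair
skeleton_length_px <- function(skel) {
  if (!is.matrix(skel)) skel <- matrix(skel, nrow = 1)
  if (!any(skel)) return(0)
  nr <- nrow(skel); nc <- ncol(skel)
  if (nr < 2 || nc < 2) return(max(0, sum(skel) - 1))
  n_orth <- sum(skel[-nr, ] & skel[-1, ]) + sum(skel[, -nc] & skel[, -1])
  d1 <- skel[-nr, -nc] & skel[-1, -1] & !(skel[-nr, -1] | skel[-1, -nc])
  d2 <- skel[-1, -nc] & skel[-nr, -1] & !(skel[-nr, -nc] | skel[-1, -1])
  n_orth + sqrt(2) * (sum(d1) + sum(d2))
}
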