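#' Center of mass of a monomer in one frame
#'
#' @param frame Atoms x 3 coordinate matrix of the whole system (nm).
#' @param topology An [assembly_topology()].
#' @param monomer_id Monomer id.
#' @param weights Optional per-atom masses overriding the topology masses.
#' @return Length-3 mass-weighted mean position (nm).
#' @export
monomer_com <- function(frame, topology, monomer_id, weights = NULL) {
  ids <- topology$atoms$id[topology$atoms$monomer == monomer_id]
  if (length(ids) == 0) stop("monomer ", monomer_id, " is empty")
  m <- if (is.null(weights)) topology$atoms$mass[match(ids, topology$atoms$id)]
       else weights
  if (sum(m) <= 0) stop("zero total mass")
  colSums(frame[ids, , drop = FALSE] * m) / sum(m)
}

#' Heterodimer axis in one frame
#'
#' Unit vector from the alpha-monomer center of mass to the beta-monomer
#' center of mass (alpha -> beta points toward the plus end).
#'
#' @inheritParams monomer_com
#' @param dimer_id Dimer id.
#' @return Unit length-3 vector.
#' @export
dimer_axis <- function(frame, topology, dimer_id) {
  mono <- topology$monomers[topology$monomers$dimer == dimer_id, ]
  a <- monomer_com(frame, topology, mono$id[mono$label == "alpha"])
  b <- monomer_com(frame, topology, mono$id[mono$label == "beta"])
  v <- b - a
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("coincident monomer centers of mass")
  v / nv
}

#' Bending angle between two axes
#'
#' Unsigned angle in degrees in `[0, 180]`; the dot product is clamped so
#' rounding never produces NaN.
#'
#' @param axis_i,axis_j Unit 3-vectors.
#' @return Angle in degrees.
#' @export
bending_angle <- function(axis_i, axis_j) {
  acos(max(-1, min(1, sum(axis_i * axis_j)))) * 180 / pi
}

#' Bending-angle series along protofilaments
#'
#' For the default inter-dimer variant, measures per frame the angle between
#' the monomer-COM axes of adjacent heterodimers on the same protofilament.
#' Pairs are classified by the lattice position of their outer member:
#' `plus_vs_central` when it sits at the plus end (or plus corner),
#' `minus_vs_central` at the minus end, otherwise `intra_pf_generic`.  The
#' intra-dimer variant instead measures, within each dimer, the angle between
#' the alpha-half and beta-half axes, each half's axis running between the
#' centers of mass of its two terminal atom groups.
#'
#' @param trajectory A [trajectory_set()].
#' @param topology An [assembly_topology()].
#' @param variant `"inter_dimer"` (default) or `"intra_dimer"`.
#' @param aggregate `"frame"` (one record per frame per pair, default) or
#'   `"pair"` (time-averaged angle per pair).
#' @return Object of class `bending_series`: list with `records` (data.frame:
#'   time_ps, pf, dimer_i, dimer_j, pair_class, angle_deg) and `summary`
#'   (per-class data.frame: class, n, mean_deg, sd_deg) plus `histograms`
#'   (per-class 1-degree-bin counts).
#' @export
bending_series <- function(trajectory, topology,
                           variant = c("inter_dimer", "intra_dimer"),
                           aggregate = c("frame", "pair")) {
  variant <- match.arg(variant)
  aggregate <- match.arg(aggregate)
  n_frames <- dim(trajectory$coords)[1]
  dimers <- topology$dimers

  classify <- function(cls_outer) {
    if (cls_outer %in% c("plus_end", "plus_corner")) "plus_vs_central"
    else if (cls_outer %in% c("minus_end", "minus_corner")) "minus_vs_central"
    else "intra_pf_generic"
  }

  if (variant == "inter_dimer") {
    pairs <- do.call(rbind, lapply(split(dimers, dimers$pf), function(dd) {
      dd <- dd[order(dd$layer), ]
      if (nrow(dd) < 2) return(NULL)
      i <- seq_len(nrow(dd) - 1)
      cls <- vapply(i, function(j) {
        # the member closer to an end determines the class
        ci <- dd$position_class[j]; cj <- dd$position_class[j + 1]
        outer <- if (cj %in% c("plus_end", "plus_corner")) cj
                 else if (ci %in% c("minus_end", "minus_corner")) ci
                 else "central"
        classify(outer)
      }, "")
      data.frame(pf = dd$pf[1], dimer_i = dd$id[i], dimer_j = dd$id[i + 1],
                 pair_class = cls, stringsAsFactors = FALSE)
    }))
  } else {
    pairs <- data.frame(pf = dimers$pf, dimer_i = dimers$id,
                        dimer_j = dimers$id,
                        pair_class = vapply(dimers$position_class, classify, ""),
                        stringsAsFactors = FALSE)
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- data.frame(pf = integer(0), dimer_i = integer(0),
                        dimer_j = integer(0), pair_class = character(0))
  }

  # mass-weighted per-monomer COMs per frame via grouped sums
  prot <- topology$atoms[topology$atoms$monomer > 0, ]
  grp <- prot$monomer
  mass <- prot$mass
  mono_ids <- sort(unique(grp))
  mtot <- rowsum(mass, grp)[, 1]
  axes_of_frame <- function(frame) {
    xyz <- frame[prot$id, , drop = FALSE] * mass
    com <- rowsum(xyz, grp) / mtot
    rownames(com) <- mono_ids
    com
  }
  half_axes <- NULL
  if (variant == "intra_dimer") {
    # split each monomer's atoms into two terminal groups by atom id
    half_grp <- stats::ave(seq_along(grp), grp, FUN = function(i) {
      as.integer(seq_along(i) > length(i) / 2)
    })
    key <- paste(grp, half_grp, sep = ".")
    mtot_h <- rowsum(mass, key)[, 1]
    half_axes <- function(frame) {
      xyz <- frame[prot$id, , drop = FALSE] * mass
      com <- rowsum(xyz, key) / mtot_h
      lo <- com[paste(mono_ids, 0, sep = "."), , drop = FALSE]
      hi <- com[paste(mono_ids, 1, sep = "."), , drop = FALSE]
      v <- hi - lo
      v / sqrt(rowSums(v^2))
    }
  }

  records <- vector("list", n_frames)
  mono <- topology$monomers
  alpha_of <- mono$id[mono$label == "alpha"][match(dimers$id,
                mono$dimer[mono$label == "alpha"])]
  beta_of <- mono$id[mono$label == "beta"][match(dimers$id,
                mono$dimer[mono$label == "beta"])]
  for (f in seq_len(n_frames)) {
    frame <- trajectory$coords[f, , ]
    if (nrow(pairs) == 0) { records[[f]] <- NULL; next }
    if (variant == "inter_dimer") {
      com <- axes_of_frame(frame)
      v <- com[as.character(beta_of), , drop = FALSE] -
           com[as.character(alpha_of), , drop = FALSE]
      v <- v / sqrt(rowSums(v^2))
      rownames(v) <- dimers$id
      vi <- v[as.character(pairs$dimer_i), , drop = FALSE]
      vj <- v[as.character(pairs$dimer_j), , drop = FALSE]
    } else {
      hv <- half_axes(frame)
      rownames(hv) <- mono_ids
      vi <- hv[as.character(alpha_of[match(pairs$dimer_i, dimers$id)]), ,
               drop = FALSE]
      vj <- hv[as.character(beta_of[match(pairs$dimer_j, dimers$id)]), ,
               drop = FALSE]
    }
    dots <- pmin(pmax(rowSums(vi * vj), -1), 1)
    records[[f]] <- data.frame(
      time_ps = trajectory$times[f], pf = pairs$pf,
      dimer_i = pairs$dimer_i, dimer_j = pairs$dimer_j,
      pair_class = pairs$pair_class,
      angle_deg = acos(dots) * 180 / pi,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, records)
  if (is.null(records)) {
    records <- data.frame(time_ps = numeric(0), pf = integer(0),
                          dimer_i = integer(0), dimer_j = integer(0),
                          pair_class = character(0), angle_deg = numeric(0))
  }
  if (aggregate == "pair" && nrow(records) > 0) {
    key <- paste(records$pf, records$dimer_i, records$dimer_j)
    agg <- do.call(rbind, lapply(split(records, key), function(r) {
      out <- r[1, ]
      out$angle_deg <- mean(r$angle_deg)
      out$time_ps <- NA_real_
      out
    }))
    records <- agg[order(agg$pf, agg$dimer_i), ]
    rownames(records) <- NULL
  }
  summary <- do.call(rbind, lapply(split(records, records$pair_class),
    function(r) {
      data.frame(class = r$pair_class[1], n = nrow(r),
                 mean_deg = mean(r$angle_deg),
                 sd_deg = if (nrow(r) > 1) stats::sd(r$angle_deg) else 0,
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  histograms <- lapply(split(records$angle_deg, records$pair_class),
    function(a) {
      h <- graphics::hist(a, breaks = seq(0, 180, by = 1), plot = FALSE)
      data.frame(angle_deg = h$mids, count = h$counts)
    })
  structure(list(records = records, summary = summary,
                 histograms = histograms, variant = variant),
            class = "bending_series")
}

#' @export
print.bending_series <- function(x, ...) {
  cat(sprintf("bending_series (%s): %d records\n", x$variant, nrow(x$records)))
  if (!is.null(x$summary) && nrow(x$summary) > 0) print(x$summary)
  invisible(x)
}
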