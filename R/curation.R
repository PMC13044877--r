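#' Consolidate isotopologue features into monoisotopic features
#'
#' Groups coeluting MS1 features spaced by the 13C isotope mass difference
#' (1.003355/z Da, charges per config) into isotope clusters and keeps the
#' monoisotopic (lowest-m/z) member of each cluster.  Cluster seeding is
#' greedy by descending intensity (ties broken by ascending m/z); each
#' feature may join only one cluster, so the operation is deterministic and
#' idempotent.  A monotone-decreasing envelope is expected for small
#' molecules but only logged when violated, never enforced.
#'
#' @param features feature data.frame ([readFeatureTable()] schema), one
#'   polarity.
#' @param cfg a [curationConfig()].
#' @return list with `features` (monoisotopic representatives plus
#'   unclustered features, input order preserved) and `clusters`
#'   (data.frame: `cluster`, `feature_id`, `mz`, `intensity`, `charge`,
#'   `is_monoisotopic`).
#' @export
#' @examples
#' f <- data.frame(feature_id = c("a", "b"), mz = c(300.1, 301.103355),
#'                 rt_min = c(5, 5), intensity = c(100, 20),
#'                 polarity = "positive", charge = NA_integer_)
#' deisotope(f, curationConfig())$features
deisotope <- function(features, cfg = curationConfig()) {
  emptyClusters <- data.frame(cluster = integer(0), feature_id = character(0),
                              mz = numeric(0), intensity = numeric(0),
                              charge = integer(0),
                              is_monoisotopic = logical(0),
                              stringsAsFactors = FALSE)
  if (nrow(features) == 0L)
    return(list(features = features, clusters = emptyClusters))
  if (length(unique(features$polarity)) > 1L)
    stop("deisotope() expects features of a single polarity")

  ord <- order(-features$intensity, features$mz)
  assigned <- rep(NA_integer_, nrow(features))   # cluster id per feature
  clusters <- list()
  cid <- 0L
  for (i in ord) {
    if (!is.na(assigned[i])) next
    best <- NULL
    for (z in sort(cfg$charges)) {
      members <- i
      for (k in seq_len(cfg$max_isotopes)) {
        expect <- features$mz[i] + k * .C13_SPACING / z
        cand <- which(is.na(assigned) &
                        abs(features$mz - expect) <= .ppmTol(expect, cfg$ppm) &
                        abs(features$rt_min - features$rt_min[i]) <=
                          cfg$rt_window_min)
        cand <- setdiff(cand, members)
        if (!length(cand)) break
        # closest in m/z wins; ties by intensity then id order
        pick <- cand[order(abs(features$mz[cand] - expect),
                           -features$intensity[cand])][1L]
        members <- c(members, pick)
      }
      if (length(members) > 1L &&
          (is.null(best) || length(members) > length(best$members)))
        best <- list(members = members, charge = z)
    }
    if (!is.null(best)) {
      cid <- cid + 1L
      assigned[best$members] <- cid
      clusters[[cid]] <- best
      env <- features$intensity[best$members]
      if (is.unsorted(rev(env), strictly = FALSE))
        message("isotope cluster ", cid,
                ": envelope is not monotone decreasing (logged only)")
    }
  }

  if (cid == 0L) {
    clusterTab <- emptyClusters
  } else {
    clusterTab <- do.call(rbind, lapply(seq_len(cid), function(k) {
      m <- clusters[[k]]$members
      data.frame(cluster = k, feature_id = features$feature_id[m],
                 mz = features$mz[m], intensity = features$intensity[m],
                 charge = clusters[[k]]$charge,
                 is_monoisotopic = features$mz[m] == min(features$mz[m]),
                 stringsAsFactors = FALSE)
    }))
  }
  # survivors: unclustered features plus the monoisotopic member of each
  # cluster (always the seed's m/z minimum by construction of the chain)
  keep <- is.na(assigned)
  for (k in seq_len(cid)) {
    m <- clusters[[k]]$members
    keep[m[which.min(features$mz[m])]] <- TRUE
  }
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(features = out, clusters = clusterTab)
}

#' Group redundant adduct features and pick one representative precursor
#'
#' Coeluting deisotoped features whose m/z values map onto a common neutral
#' mass under the configured adduct deltas (e.g. [M+H]+/[M+Na]+, delta
#' 21.98194 Da) are collapsed into one adduct group.  The highest-intensity
#' member is retained as the representative precursor; adduct species with
#' no redundant partner remain independent precursors — adducts are not
#' discarded as noise.
#'
#' @param features deisotoped feature data.frame, one polarity.
#' @param cfg a [curationConfig()]; `cfg$adducts` supplies the delta table.
#' @return list with `features` (representatives plus ungrouped features)
#'   and `groups` (data.frame: `group`, `feature_id`, `mz`, `intensity`,
#'   `adduct`, `neutral_mass`, `is_representative`).
#' @export
groupAdducts <- function(features, cfg = curationConfig()) {
  emptyGroups <- data.frame(group = integer(0), feature_id = character(0),
                            mz = numeric(0), intensity = numeric(0),
                            adduct = character(0), neutral_mass = numeric(0),
                            is_representative = logical(0),
                            stringsAsFactors = FALSE)
  if (nrow(features) == 0L)
    return(list(features = features, groups = emptyGroups))
  pol <- unique(features$polarity)
  if (length(pol) > 1L)
    stop("groupAdducts() expects features of a single polarity")
  add <- cfg$adducts[cfg$adducts$polarity == pol, , drop = FALSE]
  if (nrow(add) < 2L)
    return(list(features = features, groups = emptyGroups))

  ord <- order(-features$intensity, features$mz)
  assigned <- rep(NA_integer_, nrow(features))
  groups <- list()
  gid <- 0L
  for (i in ord) {
    if (!is.na(assigned[i])) next
    best <- NULL
    for (a in seq_len(nrow(add))) {           # hypothesis: seed is adduct a
      neutral <- features$mz[i] - add$delta[a]
      if (neutral <= 0) next
      members <- i; labels <- add$label[a]
      coel <- which(is.na(assigned) &
                      abs(features$rt_min - features$rt_min[i]) <=
                        cfg$rt_window_min)
      coel <- setdiff(coel, i)
      for (j in coel) {
        for (b in seq_len(nrow(add))) {
          if (add$label[b] %in% labels) next  # one feature per adduct form
          expect <- neutral + add$delta[b]
          if (abs(features$mz[j] - expect) <= .ppmTol(expect, cfg$ppm)) {
            members <- c(members, j); labels <- c(labels, add$label[b])
            break
          }
        }
      }
      if (length(members) > 1L &&
          (is.null(best) || length(members) > length(best$members)))
        best <- list(members = members, labels = labels, neutral = neutral)
    }
    if (!is.null(best)) {
      gid <- gid + 1L
      assigned[best$members] <- gid
      groups[[gid]] <- best
    }
  }

  if (gid == 0L) {
    groupTab <- emptyGroups
  } else {
    groupTab <- do.call(rbind, lapply(seq_len(gid), function(k) {
      g <- groups[[k]]
      m <- g$members
      data.frame(group = k, feature_id = features$feature_id[m],
                 mz = features$mz[m], intensity = features$intensity[m],
                 adduct = g$labels, neutral_mass = g$neutral,
                 is_representative =
                   features$intensity[m] == max(features$intensity[m]),
                 stringsAsFactors = FALSE)
    }))
  }
  keep <- is.na(assigned)
  for (k in seq_len(gid)) {
    m <- groups[[k]]$members
    keep[m[which.max(features$intensity[m])]] <- TRUE
  }
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(features = out, groups = groupTab)
}
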