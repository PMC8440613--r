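## Reef seascape colour dissimilarity: 64-bin colour signatures compared by
## earth mover's distance (optimal transport with Euclidean ground cost
## between bin centroids), plus the similarity-ordered distance matrix.

#' Build the colour signature of a reef image
#'
#' Bins the image with 4 regions per channel (4^3 = 64 possible bins, the
#' wider histogram used for hue-diverse seascapes), applies the same 1%
#' rare-bin rule as organism images, and renormalises weights to total mass
#' 1 so signatures are directly comparable under the earth mover's distance.
#'
#' @inheritParams binImage
#' @param threshold rare-bin exclusion threshold
#' @param reefId identifier recorded on the signature; defaults to the file
#'   name without extension
#' @return a [ColourSignature-class]
#' @export
buildSignature <- function(image, binsPerChannel = 4, threshold = 0.01,
                           reefId = NULL, bgColour = NULL) {
  if (is.null(reefId)) {
    reefId <- if (is.character(image))
      tools::file_path_sans_ext(basename(image)) else "reef"
  }
  h <- excludeRareBins(binImage(image, binsPerChannel = binsPerChannel,
                                bgColour = bgColour), threshold = threshold)
  bins <- data.frame(r = h@bins$r, g = h@bins$g, b = h@bins$b,
                     weight = h@bins$proportion)
  new("ColourSignature", reefId = as.character(reefId), bins = bins)
}

## Min-cost flow on the dense bipartite transportation graph by successive
## shortest paths with Johnson potentials (Dijkstra on reduced costs).
## Arcs are uncapacitated forwards; residual (backward) arcs are capped by
## the current flow.  Supplies and demands sum to the same total.
.transportCost <- function(cost, supply, demand, tol = 1e-12) {
  m <- length(supply)
  n <- length(demand)
  flow <- matrix(0, m, n)
  potS <- numeric(m)
  potD <- numeric(n)
  remS <- supply
  remD <- demand
  maxIter <- 4L * (m + n) * (m + n) + 64L
  iter <- 0L
  while (sum(remS) > tol) {
    iter <- iter + 1L
    if (iter > maxIter)
      stop("transportation solver failed to converge", call. = FALSE)
    distS <- ifelse(remS > tol, 0, Inf)
    distD <- rep(Inf, n)
    prevD <- integer(n)   # supply node reached via forward arc
    prevS <- integer(m)   # demand node reached via backward arc
    doneS <- rep(FALSE, m)
    doneD <- rep(FALSE, n)
    repeat {
      ms <- suppressWarnings(min(distS[!doneS]))
      md <- suppressWarnings(min(distD[!doneD]))
      if (!is.finite(min(ms, md))) break
      if (ms <= md) {
        i <- which(!doneS)[which.min(distS[!doneS])]
        doneS[i] <- TRUE
        rc <- pmax(cost[i, ] + potS[i] - potD, 0)  # forward reduced costs
        nd <- distS[i] + rc
        upd <- !doneD & nd < distD - 1e-15
        distD[upd] <- nd[upd]
        prevD[upd] <- i
      } else {
        j <- which(!doneD)[which.min(distD[!doneD])]
        doneD[j] <- TRUE
        has <- flow[, j] > tol & !doneS
        if (any(has)) {
          rc <- pmax(-cost[, j] + potD[j] - potS, 0)  # backward reduced costs
          nd <- distD[j] + rc
          upd <- has & nd < distS - 1e-15
          distS[upd] <- nd[upd]
          prevS[upd] <- j
        }
      }
    }
    cand <- which(remD > tol & is.finite(distD))
    if (!length(cand))
      stop("transportation solver: no augmenting path (unbalanced masses?)",
           call. = FALSE)
    t <- cand[which.min(distD[cand])]
    dt <- distD[t]
    potS <- potS + pmin(ifelse(is.finite(distS), distS, dt), dt)
    potD <- potD + pmin(ifelse(is.finite(distD), distD, dt), dt)
    ## trace the alternating path back from demand t
    pathF <- matrix(0L, 0L, 2L)  # forward arcs (i, j)
    pathB <- matrix(0L, 0L, 2L)  # backward arcs (i, j)
    j <- t
    repeat {
      i <- prevD[j]
      pathF <- rbind(pathF, c(i, j))
      if (prevS[i] == 0L) break
      j <- prevS[i]
      pathB <- rbind(pathB, c(i, j))
    }
    delta <- min(remS[pathF[nrow(pathF), 1]], remD[t])
    if (nrow(pathB))
      delta <- min(delta, min(flow[pathB]))
    flow[pathF] <- flow[pathF] + delta
    if (nrow(pathB)) flow[pathB] <- flow[pathB] - delta
    remS[pathF[nrow(pathF), 1]] <- remS[pathF[nrow(pathF), 1]] - delta
    remD[t] <- remD[t] - delta
  }
  sum(flow * cost)
}

.groundCost <- function(a, b, ground) {
  ca <- binCentroids(a)
  cb <- binCentroids(b)
  if (ground == "Lab") {
    ca <- grDevices::convertColor(ca / 255, from = "sRGB", to = "Lab")
    cb <- grDevices::convertColor(cb / 255, from = "sRGB", to = "Lab")
  }
  ## direct differences (not the |x|^2 - 2xy + |y|^2 expansion): identical
  ## centroids must yield an exactly zero ground cost
  sqrt(outer(ca[, 1], cb[, 1], "-")^2 + outer(ca[, 2], cb[, 2], "-")^2 +
       outer(ca[, 3], cb[, 3], "-")^2)
}

#' Earth mover's distance between two colour signatures
#'
#' The minimum transportation cost to transform one mass-1 colour signature
#' into the other, with ground cost the Euclidean distance between bin
#' centroids (in sRGB by default, the space the histograms are built in;
#' CIELAB is available).  With a metric ground cost the result is a metric
#' on signatures: symmetric, zero iff the signatures coincide as weighted
#' point sets, and obeying the triangle inequality.
#'
#' @param a,b [ColourSignature-class] objects with total weight 1
#' @param ground ground-distance space, `"sRGB"` (default) or `"Lab"`
#' @return non-negative scalar distance
#' @examples
#' s1 <- new("ColourSignature", reefId = "a",
#'           bins = data.frame(r = 0, g = 0, b = 0, weight = 1))
#' s2 <- new("ColourSignature", reefId = "b",
#'           bins = data.frame(r = 255, g = 0, b = 0, weight = 1))
#' emd(s1, s2)  # 255: cost of moving the point mass
#' @export
emd <- function(a, b, ground = c("sRGB", "Lab")) {
  stopifnot(is(a, "ColourSignature"), is(b, "ColourSignature"))
  ground <- match.arg(ground)
  if (nrow(a@bins) == 0L || nrow(b@bins) == 0L)
    stop("empty signature", call. = FALSE)
  cost <- .groundCost(a, b, ground)
  .transportCost(cost, binWeights(a), binWeights(b))
}

#' Pairwise reef colour distance matrix, ordered by similarity
#'
#' Computes all pairwise earth mover's distances between the signatures and
#' orders the matrix by average-linkage agglomerative clustering of the
#' distances, the ordering used for heatmap display.
#'
#' @param signatures list of [ColourSignature-class] objects with unique ids
#' @inheritParams emd
#' @return a [ReefDistanceMatrix-class]
#' @export
reefDistanceMatrix <- function(signatures, ground = c("sRGB", "Lab")) {
  ground <- match.arg(ground)
  if (length(signatures) < 2L) stop("need >= 2 signatures", call. = FALSE)
  ids <- vapply(signatures, reefId, "")
  if (anyDuplicated(ids))
    stop("duplicate reef ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  p <- length(ids)
  v <- matrix(0, p, p, dimnames = list(ids, ids))
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      d <- emd(signatures[[i]], signatures[[j]], ground = ground)
      v[i, j] <- d
      v[j, i] <- d
    }
  }
  tree <- hclust(as.dist(v), method = "average")
  new("ReefDistanceMatrix", ids = ids, values = v,
      ordering = as.integer(tree$order), tree = tree)
}

#' Write a reef distance matrix and its similarity ordering
#'
#' @param x a [ReefDistanceMatrix-class]
#' @param file CSV path for the square matrix (ids as header and first
#'   column)
#' @param orderFile optional path for the similarity ordering, one reef id
#'   per line
#' @return invisibly, `file`
#' @export
writeDistanceMatrix <- function(x, file, orderFile = NULL) {
  stopifnot(is(x, "ReefDistanceMatrix"))
  df <- data.frame(reef = x@ids, x@values, check.names = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  if (!is.null(orderFile))
    writeLines(x@ids[x@ordering], orderFile)
  invisible(file)
}
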