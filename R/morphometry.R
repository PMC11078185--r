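#' Circularity index of a section outline
#'
#' `CI = 4 * pi * area / perimeter^2`, the isoperimetric quotient: 1.0 for
#' a perfect circle, approaching 0 for increasingly elongated shapes. Area
#' by the shoelace formula, perimeter as the vertex-to-vertex Euclidean sum
#' including the closing edge. Used to quantify mechanical deformation of
#' the cord after chronic implantation.
#'
#' The outline must be a simple (non-self-intersecting) closed polygon;
#' self-intersection is checked exhaustively only for outlines of up to
#' 256 vertices, and is otherwise the caller's responsibility.
#'
#' @param outline two-column matrix (x, y in micrometres), vertices in
#'   outline order, without a repeated closing vertex.
#' @return The circularity index, a number in (0, 1\] up to discretization
#'   tolerance.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' circularity(sq)  # pi / 4
#' @export
circularity <- function(outline) {
  outline <- as.matrix(outline)
  if (ncol(outline) != 2L) stop("outline must have two columns (x, y)")
  if (nrow(outline) < 3L) stop("a polygon needs at least 3 vertices")
  if (anyNA(outline) || !all(is.finite(outline)))
    stop("outline contains non-finite vertices")
  x <- outline[, 1]; y <- outline[, 2]
  n <- nrow(outline)
  nxt <- c(2:n, 1L)
  seg <- sqrt((x[nxt] - x)^2 + (y[nxt] - y)^2)
  if (any(seg == 0)) stop("degenerate polygon: duplicated consecutive vertices")
  perimeter <- sum(seg)
  area <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  if (area == 0 || perimeter == 0)
    stop("degenerate polygon: zero area or perimeter")
  if (n <= 256L && !is_simple_polygon(x, y))
    stop("outline is self-intersecting")
  4 * pi * area / perimeter^2
}

is_simple_polygon <- function(x, y) {
  n <- length(x)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next   # adjacent through the closing edge
      i2 <- if (i == n) 1L else i + 1L
      j2 <- if (j == n) 1L else j + 1L
      if (seg_int(c(x[i], y[i]), c(x[i2], y[i2]),
                  c(x[j], y[j]), c(x[j2], y[j2])))
        return(FALSE)
    }
  }
  TRUE
}

#' Per-animal mean circularity
#'
#' Protocol: three sections per animal, each measured three times, so nine
#' measurements averaged per animal. Fewer measurements are accepted with
#' a warning.
#'
#' @param measurements numeric circularity indices for one animal.
#' @return Their arithmetic mean.
#' @export
animal_mean <- function(measurements) {
  measurements <- measurements[!is.na(measurements)]
  if (length(measurements) == 0L) stop("no measurements")
  if (length(measurements) != 9L)
    warning(sprintf("expected 9 measurements per animal, got %d",
                    length(measurements)))
  mean(measurements)
}

#' One-sample group comparison of circularity means
#'
#' Two-tailed one-sample t test of the per-animal mean circularity indices
#' against a control reference value, with the 95% confidence interval of
#' the group mean.
#'
#' @param animal_means per-animal mean circularity indices (>= 2).
#' @param reference_mean control reference circularity.
#' @return List: `t`, `p`, `df`, `ci` (95% CI of the mean), `mean`, `sd`,
#'   `n`, `reference_mean`.
#' @export
group_test <- function(animal_means, reference_mean) {
  animal_means <- animal_means[!is.na(animal_means)]
  if (length(animal_means) < 2L) stop("need >= 2 animal means")
  if (sd(animal_means) == 0) {
    eq <- mean(animal_means) == reference_mean
    return(list(t = if (eq) 0 else NA_real_, p = if (eq) 1 else NA_real_,
                df = length(animal_means) - 1,
                ci = rep(mean(animal_means), 2), mean = mean(animal_means),
                sd = 0, n = length(animal_means),
                reference_mean = reference_mean, degenerate = !eq))
  }
  tt <- t.test(animal_means, mu = reference_mean)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), ci = as.numeric(tt$conf.int),
       mean = mean(animal_means), sd = sd(animal_means),
       n = length(animal_means), reference_mean = reference_mean,
       degenerate = FALSE)
}

#' Read section outlines from a vertex CSV
#'
#' Columns `animal,section,repeat,x_um,y_um`, vertices in outline order.
#'
#' @param path CSV file path.
#' @return A list of outline matrices, named `animal/section/repeat`, with
#'   a `meta` attribute data.frame (`animal`, `section`, `repeat`).
#' @export
read_outlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "section", "repeat.", "x_um", "y_um")
  names(df)[names(df) == "repeat."] <- "repeat_id"
  if (!all(c("animal", "section", "x_um", "y_um") %in% names(df)))
    stop("outline CSV missing required columns")
  if (!"repeat_id" %in% names(df)) {
    rp <- intersect(c("repeat", "rep"), names(df))
    if (!length(rp)) stop("outline CSV missing the repeat column")
    names(df)[names(df) == rp[1]] <- "repeat_id"
  }
  key <- interaction(df$animal, df$section, df$repeat_id, drop = TRUE,
                     sep = "/")
  out <- lapply(split(df, key), function(d) cbind(x = d$x_um, y = d$y_um))
  meta <- unique(df[, c("animal", "section", "repeat_id")])
  attr(out, "meta") <- meta
  out
}

#' Trace the outline of a binary mask (marching squares)
#'
#' Convenience helper turning a rasterized section mask into a polygon
#' outline by following the boundary of its largest foreground region with
#' a marching-squares walk on the pixel-corner grid. The raw walk moves
#' only horizontally/vertically, which overstates the perimeter of smooth
#' shapes (a staircase measures city-block, not Euclidean, length), so
#' `smooth_iter` corner-cutting passes (each vertex replaced by the
#' midpoint to its successor) are applied; 0 returns the raw pixel-edge
#' contour.
#'
#' @param mask logical or 0/1 matrix (rows = y, columns = x).
#' @param spacing_um pixel size in micrometres (default 1).
#' @param smooth_iter midpoint smoothing passes (default 2).
#' @return Two-column outline matrix suitable for [circularity()].
#' @export
mask_to_outline <- function(mask, spacing_um = 1, smooth_iter = 2) {
  m <- (as.matrix(mask) != 0)
  if (!any(m)) stop("mask has no foreground pixels")
  nr <- nrow(m); nc <- ncol(m)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- m
  # cell state from its four surrounding pixels; walk the boundary
  start <- which(padded, arr.ind = TRUE)[1L, ]
  # start on the top edge of the first foreground pixel, heading right
  cy <- start[1L] - 1L; cx <- start[2L] - 1L
  pix <- function(y, x) y >= 1L && y <= nr + 2L && x >= 1L && x <= nc + 2L &&
    padded[y, x]
  path <- matrix(NA_real_, 0, 2)
  dir <- "R"
  y <- cy; x <- cx
  repeat {
    path <- rbind(path, c(x, y))
    # corner (y, x) of the pixel grid: pixels around it
    tl <- pix(y, x); tr <- pix(y, x + 1L)
    bl <- pix(y + 1L, x); br <- pix(y + 1L, x + 1L)
    state <- tl * 8L + tr * 4L + br * 2L + bl * 1L
    dir <- switch(as.character(state),
                  "1" = "D", "2" = "R", "3" = "R", "4" = "U",
                  "5" = if (dir == "R") "U" else "D",
                  "6" = "U", "7" = "U", "8" = "L", "9" = "D",
                  "10" = if (dir == "U") "L" else "R",
                  "11" = "R", "12" = "L", "13" = "D", "14" = "L",
                  stop("marching squares: invalid state"))
    if (dir == "R") x <- x + 1L
    else if (dir == "L") x <- x - 1L
    else if (dir == "U") y <- y - 1L
    else y <- y + 1L
    if (y == cy && x == cx) break
    if (nrow(path) > 4L * (nr + 2L) * (nc + 2L))
      stop("marching squares failed to close the contour")
  }
  for (it in seq_len(smooth_iter)) {
    nxt <- rbind(path[-1L, , drop = FALSE], path[1L, , drop = FALSE])
    path <- (path + nxt) / 2
  }
  path * spacing_um
}
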