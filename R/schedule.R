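#' Canonical stimulus image set
#'
#' Builds the abstract stimulus inventory: `n_per_category` images from each
#' of the three categories (spiders, scorpions, short-horned grasshoppers),
#' each labelled with a colour group used for pair matching. Image content is
#' out of scope; images are identities plus labels.
#'
#' Colour groups are laid out so that a perfect colour matching exists for
#' the three pair-type blocks: each category's images split into two halves
#' whose colours equal those of the partner category's corresponding half
#' (spiders share one half with grasshoppers and the other with scorpions,
#' and so on around the triangle).
#'
#' @param n_per_category images per category (default 12, the full set).
#' @return Data frame `image_id, category, color_group`.
#' @export
#' @examples
#' head(stimulus_images())
stimulus_images <- function(n_per_category = 12L) {
  stopifnot(n_per_category >= 1)
  half <- ceiling(n_per_category / 2)
  # shared colour halves: A = spider/grasshopper, B = scorpion/grasshopper,
  # C = spider/scorpion
  A <- rep(c("black", "brown", "sandy"), each = 2)
  B <- rep(c("grey", "disruptive", "reddish"), each = 2)
  C <- rep(c("black", "disruptive", "sandy"), each = 2)
  halves <- list(
    spider = c(rep(A, length.out = half),
               rep(C, length.out = n_per_category - half)),
    grasshopper = c(rep(A, length.out = half),
                    rep(B, length.out = n_per_category - half)),
    scorpion = c(rep(B, length.out = half),
                 rep(C, length.out = n_per_category - half)))
  per_cat <- function(cat) data.frame(
    image_id = sprintf("%s_%02d", cat, seq_len(n_per_category)),
    category = cat,
    color_group = halves[[cat]],
    stringsAsFactors = FALSE)
  do.call(rbind, lapply(.animal_levels, per_cat))
}

#' Pair stimulus images across categories
#'
#' Assembles cross-category pairs so that every image is used exactly once
#' and the three pair types (spider-grasshopper, scorpion-grasshopper,
#' scorpion-spider) are equally frequent. With the full 36-image set this
#' yields 18 pairs. Within each pair type, images are matched by
#' `color_group` where possible; when colour matching is impossible the
#' pairing falls back to arbitrary within-type assignment with a warning.
#'
#' @param images data frame from [stimulus_images()] (columns `image_id`,
#'   `category`, `color_group`). Category counts must be equal and even.
#' @return Data frame of pairs with columns `pair_id, base_pair_id,
#'   pair_type, orientation, left_image, right_image, left_category,
#'   right_category`, all `orientation == "original"`. The left/right
#'   assignment places the first-named animal of the pair type on the left.
#' @export
build_pairs <- function(images) {
  stopifnot(is.data.frame(images),
            all(c("image_id", "category", "color_group") %in% names(images)))
  if (anyDuplicated(images$image_id)) stop("duplicated image ids")
  if (!setequal(unique(images$category), .animal_levels))
    stop("images must cover exactly the categories: ",
         paste(.animal_levels, collapse = ", "))
  counts <- table(factor(images$category, .animal_levels))
  if (length(unique(as.integer(counts))) != 1L)
    stop("unequal category counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  n <- as.integer(counts[1])
  if (n %% 2L != 0L)
    stop("category counts must be even to split across two pair types")
  k <- n %/% 2L

  pools <- split(images, factor(images$category, .animal_levels))
  take <- function(cat, partner_cat, k) {
    # pick k images from each pool, pairing same colour groups first
    a <- pools[[cat]]; b <- pools[[partner_cat]]
    pick_a <- integer(0); pick_b <- integer(0)
    for (col in intersect(a$color_group, b$color_group)) {
      if (length(pick_a) >= k) break
      ia <- setdiff(which(a$color_group == col), pick_a)
      ib <- setdiff(which(b$color_group == col), pick_b)
      m <- min(length(ia), length(ib), k - length(pick_a))
      if (m > 0) { pick_a <- c(pick_a, ia[seq_len(m)])
                   pick_b <- c(pick_b, ib[seq_len(m)]) }
    }
    if (length(pick_a) < k) {
      warning("unpairable color groups for ", cat, "/", partner_cat,
              "; falling back to arbitrary within-type pairing",
              call. = FALSE)
      ia <- setdiff(seq_len(nrow(a)), pick_a)
      ib <- setdiff(seq_len(nrow(b)), pick_b)
      need <- k - length(pick_a)
      pick_a <- c(pick_a, ia[seq_len(need)])
      pick_b <- c(pick_b, ib[seq_len(need)])
    }
    pools[[cat]] <<- a[-pick_a, , drop = FALSE]
    pools[[partner_cat]] <<- b[-pick_b, , drop = FALSE]
    data.frame(left_image = a$image_id[pick_a],
               right_image = b$image_id[pick_b],
               left_category = cat, right_category = partner_cat,
               stringsAsFactors = FALSE)
  }
  blocks <- list(
    cbind(pair_type = "spider-grasshopper", take("spider", "grasshopper", k)),
    cbind(pair_type = "scorpion-grasshopper",
          take("scorpion", "grasshopper", k)),
    cbind(pair_type = "scorpion-spider", take("scorpion", "spider", k)))
  pairs <- do.call(rbind, blocks)
  pairs$base_pair_id <- sprintf("bp%02d", seq_len(nrow(pairs)))
  pairs$pair_id <- paste0(pairs$base_pair_id, "_o")
  pairs$orientation <- "original"
  rownames(pairs) <- NULL
  pairs[, c("pair_id", "base_pair_id", "pair_type", "orientation",
            "left_image", "right_image", "left_category", "right_category")]
}

#' Mirror stimulus pairs horizontally
#'
#' For each original pair, adds the horizontally mirrored version (left and
#' right images swapped), doubling the slide count: 18 pairs become 36
#' slides. A pair and its mirror share `base_pair_id`.
#'
#' @param pairs data frame from [build_pairs()] with all
#'   `orientation == "original"`.
#' @return Data frame of slides (originals followed by mirrors), with
#'   `pair_id` suffixes `_o` / `_m`.
#' @export
mirror_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(pairs$orientation == "original"))
  if (anyDuplicated(pairs$base_pair_id)) stop("duplicated base pair ids")
  m <- pairs
  m$pair_id <- paste0(m$base_pair_id, "_m")
  m$orientation <- "mirrored"
  m[, c("left_image", "right_image")] <- pairs[, c("right_image",
                                                   "left_image")]
  m[, c("left_category", "right_category")] <- pairs[, c("right_category",
                                                         "left_category")]
  out <- rbind(pairs, m)
  rownames(out) <- NULL
  out
}

#' Build a pseudo-random presentation schedule
#'
#' Orders the slides randomly subject to the interlacing constraint: a slide
#' and its horizontal mirror must be separated by at least two completely
#' different pairs, formalised as a positional separation of at least
#' `min_separation` (default 3, i.e. at least two intervening slides). The
#' order is found by seeded rejection sampling over random permutations.
#'
#' @param slides data frame from [mirror_pairs()].
#' @param seed integer seed; the schedule is a deterministic function of it.
#' @param min_separation minimal positional distance between mirror mates.
#' @param max_tries permutations attempted before giving up with an error.
#' @param slide_ms,cross_ms nominal slide and inter-slide fixation-cross
#'   durations (ms).
#' @return An object of class `presentation_schedule`: a list with the
#'   ordered `slides` data frame (with a `position` column) and the two
#'   durations.
#' @export
make_schedule <- function(slides, seed = 1L, min_separation = 3L,
                          max_tries = 10000L, slide_ms = 5000,
                          cross_ms = 2000) {
  stopifnot(is.data.frame(slides), nrow(slides) >= 2)
  ord <- .with_seed(seed, {
    found <- NULL
    for (try in seq_len(max_tries)) {
      cand <- sample.int(nrow(slides))
      if (.schedule_ok(slides$base_pair_id[cand], min_separation)) {
        found <- cand
        break
      }
    }
    found
  })
  if (is.null(ord))
    stop("no schedule satisfying the interlacing constraint found after ",
         max_tries, " tries")
  sl <- slides[ord, , drop = FALSE]
  sl$position <- seq_len(nrow(sl))
  rownames(sl) <- NULL
  structure(list(slides = sl[, c("position", setdiff(names(sl), "position"))],
                 slide_ms = slide_ms, cross_ms = cross_ms,
                 min_separation = as.integer(min_separation)),
            class = "presentation_schedule")
}

.schedule_ok <- function(base_ids, min_separation) {
  pos <- split(seq_along(base_ids), base_ids)
  all(vapply(pos, function(p)
    length(p) < 2L || min(diff(sort(p))) >= min_separation, TRUE))
}

#' Validate a presentation schedule
#'
#' Independent check of the interlacing constraint; returns a character
#' vector of violations (empty when valid).
#'
#' @param schedule a `presentation_schedule`.
#' @param min_separation minimal positional distance between slides sharing
#'   a base pair.
#' @export
validate_schedule <- function(schedule,
                              min_separation = schedule$min_separation) {
  sl <- schedule$slides
  issues <- character(0)
  for (bp in unique(sl$base_pair_id)) {
    p <- sort(which(sl$base_pair_id == bp))
    if (length(p) >= 2L && min(diff(p)) < min_separation)
      issues <- c(issues, sprintf(
        "base pair %s at positions %s: separation %d < %d", bp,
        paste(p, collapse = ","), min(diff(p)), min_separation))
  }
  issues
}

#' Reverse a presentation schedule
#'
#' Returns the same slides in exactly reversed order (used for the
#' counterbalanced half of the cohort). Positional separations are symmetric,
#' so the interlacing constraint still holds.
#'
#' @param schedule a `presentation_schedule`.
#' @export
reverse_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "presentation_schedule"))
  sl <- schedule$slides[rev(seq_len(nrow(schedule$slides))), , drop = FALSE]
  sl$position <- seq_len(nrow(sl))
  rownames(sl) <- NULL
  schedule$slides <- sl
  schedule
}

#' @export
print.presentation_schedule <- function(x, ...) {
  cat(sprintf(
    "<presentation_schedule> %d slides (%g ms each, %g ms cross), mirror-mate separation >= %d\n",
    nrow(x$slides), x$slide_ms, x$cross_ms, x$min_separation))
  print(head(x$slides, 4))
  if (nrow(x$slides) > 4) cat("...\n")
  invisible(x)
}

#' Read / write a schedule slide table
#'
#' CSV interchange for schedules: one row per position with slide identity,
#' base pair, pair type, orientation and the left/right image ids and
#' categories.
#'
#' @param schedule a `presentation_schedule`.
#' @param path file path.
#' @param slide_ms,cross_ms durations used when reading back.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(schedule$slides, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, slide_ms = 5000, cross_ms = 2000) {
  sl <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "pair_id", "base_pair_id", "pair_type",
            "orientation", "left_image", "right_image")
  if (!all(need %in% names(sl)))
    stop("schedule file lacks columns: ",
         paste(setdiff(need, names(sl)), collapse = ", "))
  sl <- sl[order(sl$position), , drop = FALSE]
  rownames(sl) <- NULL
  structure(list(slides = sl, slide_ms = slide_ms, cross_ms = cross_ms,
                 min_separation = 3L),
            class = "presentation_schedule")
}

# evaluate expr with a temporary RNG seed, restoring global state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
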