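#' NEMS-S scoring
#'
#' The Nutrition Environment Measures Survey in Stores (NEMS-S) rates the
#' availability, price, and quality of healthy food options in a retail store.
#' Availability items are scored 0--6 each; price comparison items (healthier
#' option vs. regular option) are scored -1--2 each; fresh produce quality is a
#' single subjective score 0--6. Sub-scores are item sums and the total score
#' is the sum of the three sub-scores. With the default instrument (5
#' availability items, 9 price items) the sub-score ranges are 0--30
#' (availability), -9--18 (price), 0--6 (quality), and the total ranges
#' -9--54.
#'
#' Item counts are configurable: the printed sub-score ranges pin down the
#' default counts (5 x 6 = 30; 9 x 2 = 18; 9 x -1 = -9) but any instrument
#' with the same per-item scales is accepted, and sub-score range validation
#' in [score_total()] adapts accordingly.
#'
#' @name nems_scoring
NULL

.check_items <- function(items, lo, hi, what) {
  if (length(items) == 0L) stop(what, " items must be non-empty", call. = FALSE)
  if (anyNA(items) || !is.numeric(items)) {
    stop(what, " items must be numeric and non-missing", call. = FALSE)
  }
  if (any(items != round(items))) {
    bad <- which(items != round(items))[1L]
    stop(what, " item ", bad, " is not an integer score", call. = FALSE)
  }
  bad <- which(items < lo | items > hi)
  if (length(bad)) {
    stop(sprintf("%s item %d out of range [%d, %d]: %g",
                 what, bad[1L], lo, hi, items[bad[1L]]), call. = FALSE)
  }
  invisible(as.integer(items))
}

#' Availability sub-score
#'
#' Sum of availability item scores, each on the 0--6 scale. With the default
#' five-item instrument the result lies in 0--30; higher means more healthier
#' foods stocked.
#'
#' @param items integer vector of availability item scores, each in 0--6.
#' @return integer sub-score.
#' @export
#' @examples
#' score_availability(c(6, 6, 6, 6, 6)) # 30, the best case
score_availability <- function(items) {
  sum(.check_items(items, 0L, 6L, "availability"))
}

#' Price sub-score
#'
#' Sum of price comparison item scores, each on the -1--2 scale (negative when
#' the healthier option costs more). With the default nine-item instrument the
#' result lies in -9--18.
#'
#' @param items integer vector of price item scores, each in -1--2.
#' @return integer sub-score.
#' @export
score_price <- function(items) {
  sum(.check_items(items, -1L, 2L, "price"))
}

#' Quality sub-score
#'
#' Single subjective rating of fresh fruit and vegetable quality, 0--6
#' (acceptable vs. rotten/bruised/discoloured).
#'
#' @param item integer in 0--6.
#' @return integer sub-score.
#' @export
score_quality <- function(item) {
  if (length(item) != 1L) stop("quality is a single item", call. = FALSE)
  sum(.check_items(item, 0L, 6L, "quality"))
}

#' Total NEMS-S score
#'
#' Sum of the availability, price, and quality sub-scores. Each sub-score is
#' validated against its instrument range before summing.
#'
#' @param availability availability sub-score.
#' @param price price sub-score.
#' @param quality quality sub-score.
#' @param ranges list with elements `availability`, `price`, `quality`, each a
#'   length-2 numeric range; defaults are the standard-instrument ranges.
#' @return integer total score (default instrument: in -9--54).
#' @export
#' @examples
#' score_total(30, 18, 6)  # 54, best attainable
#' score_total(0, -9, 0)   # -9, worst attainable
score_total <- function(availability, price, quality,
                        ranges = list(availability = c(0L, 30L),
                                      price = c(-9L, 18L),
                                      quality = c(0L, 6L))) {
  chk <- function(x, rg, what) {
    if (length(x) != 1L || is.na(x) || x < rg[1L] || x > rg[2L]) {
      stop(sprintf("%s sub-score %s outside [%d, %d]", what,
                   format(x), rg[1L], rg[2L]), call. = FALSE)
    }
  }
  chk(availability, ranges$availability, "availability")
  chk(price, ranges$price, "price")
  chk(quality, ranges$quality, "quality")
  as.integer(availability + price + quality)
}

#' Score one store's item responses
#'
#' @param availability_items availability item vector (each 0--6).
#' @param price_items price item vector (each -1--2).
#' @param quality_item quality rating (0--6).
#' @return list with `availability`, `price`, `quality`, `total`.
#' @export
nems_score <- function(availability_items, price_items, quality_item) {
  a <- score_availability(availability_items)
  p <- score_price(price_items)
  q <- score_quality(quality_item)
  nq <- length(price_items)
  list(availability = a, price = p, quality = q,
       total = score_total(a, p, q,
                           ranges = list(
                             availability = c(0L, 6L * length(availability_items)),
                             price = c(-1L * nq, 2L * nq),
                             quality = c(0L, 6L))))
}

#' Batch-score a store table
#'
#' Takes a store table whose item responses live in columns `av_1..av_k`
#' (availability), `pr_1..pr_k` (price) and `quality_item`, and appends (or
#' overwrites) `availability`, `price`, `quality` and `total` columns.
#'
#' @param stores data frame of stores with item-response columns.
#' @return the input data frame with score columns appended.
#' @export
score_stores <- function(stores) {
  av_cols <- grep("^av_[0-9]+$", names(stores), value = TRUE)
  pr_cols <- grep("^pr_[0-9]+$", names(stores), value = TRUE)
  if (!length(av_cols) || !length(pr_cols) || !"quality_item" %in% names(stores)) {
    stop("stores table must have av_*, pr_* and quality_item columns", call. = FALSE)
  }
  av_cols <- av_cols[order(as.integer(sub("^av_", "", av_cols)))]
  pr_cols <- pr_cols[order(as.integer(sub("^pr_", "", pr_cols)))]
  sc <- lapply(seq_len(nrow(stores)), function(i) {
    nems_score(as.numeric(stores[i, av_cols]),
               as.numeric(stores[i, pr_cols]),
               stores$quality_item[i])
  })
  stores$availability <- vapply(sc, `[[`, integer(1), "availability")
  stores$price <- vapply(sc, `[[`, integer(1), "price")
  stores$quality <- vapply(sc, `[[`, integer(1), "quality")
  stores$total <- vapply(sc, `[[`, integer(1), "total")
  stores
}
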