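#' Stratified permuted-block randomisation
#'
#' Allocates participants 1:1 to `"FMD"` or `"control"` within strata defined
#' by sex and the weight stratum (> 100 kg vs <= 100 kg; exactly 100 kg falls
#' in the lower stratum), using permuted blocks whose sizes are drawn
#' uniformly at random from `block_sizes`. Each block is a random permutation
#' of a balanced arm sequence, so completed blocks are perfectly balanced and
#' the within-stratum arm imbalance never exceeds half the largest block size
#' at any point in the enrolment order. Deterministic given `seed`, which is
#' stored with the block trace for audit.
#'
#' @param participants Data.frame with `participant_id`, `sex`, and either
#'   `weight_kg` or a precomputed `weight_stratum` column.
#' @param block_sizes Even positive block sizes to mix (default `c(2, 4)`).
#' @param seed Integer RNG seed.
#' @return An `allocation_plan`: list with `assignments` (data.frame
#'   participant_id, stratum, arm), `block_trace` (stratum, block sizes in
#'   draw order) and `seed`.
#' @examples
#' p <- data.frame(participant_id = sprintf("P%02d", 1:8),
#'                 sex = rep(c("M", "F"), 4), weight_kg = c(90, 120) + 1:8)
#' randomize(p, seed = 1)
#' @export
randomize <- function(participants, block_sizes = c(2, 4), seed) {
  if (missing(seed)) stop("seed is required for a reproducible plan", call. = FALSE)
  if (any(block_sizes %% 2 != 0) || any(block_sizes <= 0)) {
    stop("block sizes must be positive and even for 1:1 allocation", call. = FALSE)
  }
  if (!"sex" %in% names(participants)) {
    stop("participants must carry a 'sex' column", call. = FALSE)
  }
  if (!"weight_stratum" %in% names(participants)) {
    if (!"weight_kg" %in% names(participants)) {
      stop("participants must carry 'weight_stratum' or 'weight_kg'", call. = FALSE)
    }
    participants$weight_stratum <- weight_stratum(participants$weight_kg)
  }
  stratum <- paste(participants$sex, participants$weight_stratum, sep = "/")

  set.seed(seed)
  arm <- character(nrow(participants))
  trace <- list()
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    alloc <- character(0)
    sizes <- integer(0)
    while (length(alloc) < length(idx)) {
      bs <- block_sizes[sample.int(length(block_sizes), 1)]
      block <- sample(rep(c("FMD", "control"), bs / 2))
      alloc <- c(alloc, block)
      sizes <- c(sizes, bs)
    }
    arm[idx] <- alloc[seq_along(idx)]
    trace[[s]] <- sizes
  }
  structure(list(
    assignments = data.frame(participant_id = participants$participant_id,
                             stratum = stratum, arm = arm,
                             stringsAsFactors = FALSE),
    block_trace = trace, seed = seed
  ), class = "allocation_plan")
}

#' Weight stratum used for randomisation
#'
#' `"over100kg"` for body weight strictly above 100 kg, `"upto100kg"`
#' otherwise (the boundary value 100 kg is assigned to the lower stratum).
#'
#' @param weight_kg Numeric body weight in kg.
#' @export
weight_stratum <- function(weight_kg) {
  ifelse(weight_kg > 100, "over100kg", "upto100kg")
}

#' @export
print.allocation_plan <- function(x, ...) {
  tab <- table(x$assignments$stratum, x$assignments$arm)
  cat("<allocation_plan> seed", x$seed, "\n")
  print(tab)
  invisible(x)
}
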