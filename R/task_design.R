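#' Enumerate all valid harm-allocation choice pairs
#'
#' A choice pair assigns \code{c_one} seconds of cold-pressor time to a single
#' individual or \code{c_group} seconds to each of \code{n_group} group
#' members.  A pair is valid when the harm to the one is at least the harm to
#' each group member but no more than the group's total harm:
#' \code{c_group <= c_one <= c_group * n_group}.  Under this constraint the
#' one option always minimises total harm while the group option always
#' minimises the largest individual harm, so the two options pit the
#' utilitarian strategy against the Rawlsian maximin strategy.
#'
#' @param grid numeric vector of allowed harm durations in seconds
#'   (default 30 to 180 in steps of 10).
#' @param group_sizes integer vector of allowed group sizes (default 3:4).
#' @return data.frame with columns \code{c_one}, \code{c_group},
#'   \code{n_group}, ordered by ascending \code{c_group}, then \code{c_one},
#'   then \code{n_group}.
#' @examples
#' nrow(enumerate_valid_pairs())          # 246 on the default grid
#' enumerate_valid_pairs(grid = 30, group_sizes = 3)
#' @export
enumerate_valid_pairs <- function(grid = seq(30, 180, by = 10),
                                  group_sizes = 3:4) {
  if (length(grid) == 0L || any(!is.finite(grid)) || any(grid <= 0))
    stop("'grid' must be a nonempty vector of positive harm durations")
  if (length(group_sizes) == 0L || any(group_sizes < 2))
    stop("'group_sizes' must contain integers >= 2")
  full <- expand.grid(n_group = as.integer(sort(unique(group_sizes))),
                      c_one = sort(unique(grid)),
                      c_group = sort(unique(grid)),
                      KEEP.OUT.ATTRS = FALSE)
  ok <- full$c_group <= full$c_one & full$c_one <= full$c_group * full$n_group
  out <- full[ok, c("c_one", "c_group", "n_group")]
  out <- out[order(out$c_group, out$c_one, out$n_group), ]
  rownames(out) <- NULL
  out
}

#' Default conditions of the harm-allocation task
#'
#' Every choice pair is presented three times: once with no default, once with
#' the one option as the default (implemented unless the subject acts), and
#' once with the group option as the default.
#' @return character vector of the three condition labels.
#' @export
default_conditions <- function() c("none", "one_default", "group_default")

#' Sample a harm-allocation task design
#'
#' Samples \code{n_pairs} unique valid (c_one, c_group, n_group) triples
#' without replacement, replicates each under the three default conditions,
#' and shuffles presentation order and the left/right placement of the one
#' option.  With the defaults this yields the 150-trial design
#' (50 pairs x 3 default conditions).
#'
#' The deployed task used a fixed, predetermined list of 50 pairs; this
#' function draws a reproducible stand-in from the valid set under
#' \code{seed}.  An explicit pair list (e.g. read from file) can be supplied
#' via \code{pairs} instead.
#'
#' @param n_pairs number of unique choice pairs (default 50).
#' @param grid,group_sizes passed to \code{\link{enumerate_valid_pairs}}.
#' @param seed integer seed; the design is a pure function of it.
#' @param pairs optional data.frame with columns \code{c_one}, \code{c_group},
#'   \code{n_group} overriding the sampled pairs (validated against the
#'   constraint).
#' @param alternate_sizes if TRUE, reassign group sizes to alternate 3,4,3,...
#'   across the sampled pairs (subject to validity) instead of sampling the
#'   size jointly with the pair.
#' @return data.frame of class \code{"harm_design"}: one row per trial with
#'   columns \code{trial}, \code{c_one}, \code{c_group}, \code{n_group},
#'   \code{default_cond}, \code{side_one} (screen side of the one option) and
#'   \code{pair_id}.
#' @examples
#' d <- harm_design(seed = 1)
#' nrow(d)                      # 150
#' table(d$default_cond)        # 50 each
#' @export
harm_design <- function(n_pairs = 50, grid = seq(30, 180, by = 10),
                        group_sizes = 3:4, seed = 1L, pairs = NULL,
                        alternate_sizes = FALSE) {
  valid <- enumerate_valid_pairs(grid, group_sizes)
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)[, c("c_one", "c_group", "n_group")]
    bad <- pairs$c_group > pairs$c_one | pairs$c_one > pairs$c_group * pairs$n_group
    if (any(bad))
      stop("supplied pairs violate c_group <= c_one <= c_group * n_group at rows: ",
           paste(which(bad), collapse = ", "))
  } else if (n_pairs > nrow(valid)) {
    stop("n_pairs (", n_pairs, ") exceeds the number of valid pairs (",
         nrow(valid), ")")
  }
  with_seed(seed, {
    if (is.null(pairs)) {
      pairs <- valid[sample.int(nrow(valid), n_pairs), ]
      if (alternate_sizes) {
        want <- rep_len(sort(unique(group_sizes)), n_pairs)
        ok <- pairs$c_group <= pairs$c_one & pairs$c_one <= pairs$c_group * want
        pairs$n_group[ok] <- want[ok]    # keep sampled size where alternation is invalid
      }
    }
    pairs$pair_id <- seq_len(nrow(pairs))
    conds <- default_conditions()
    des <- pairs[rep(seq_len(nrow(pairs)), times = length(conds)), ]
    des$default_cond <- rep(conds, each = nrow(pairs))
    des <- des[sample.int(nrow(des)), ]
    des$side_one <- sample(c("left", "right"), nrow(des), replace = TRUE)
    des$trial <- seq_len(nrow(des))
    rownames(des) <- NULL
    des <- des[, c("trial", "pair_id", "c_one", "c_group", "n_group",
                   "default_cond", "side_one")]
    class(des) <- c("harm_design", "data.frame")
    attr(des, "seed") <- seed
    des
  })
}

#' Validate design invariants
#'
#' Checks every trial of a design (or the trial columns of a choice dataset)
#' against the task constraints: grid membership, group size, the harm
#' inequality, and a legal default condition.
#'
#' @param design data.frame with columns \code{c_one}, \code{c_group},
#'   \code{n_group}, \code{default_cond}.
#' @param grid,group_sizes the allowed grids.
#' @return invisibly TRUE; stops with a message naming the offending rows
#'   otherwise.
#' @export
validate_design <- function(design, grid = seq(30, 180, by = 10),
                            group_sizes = 3:4) {
  need <- c("c_one", "c_group", "n_group", "default_cond")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  bad <- !(design$c_one %in% grid) | !(design$c_group %in% grid) |
    !(design$n_group %in% group_sizes) |
    design$c_group > design$c_one |
    design$c_one > design$c_group * design$n_group |
    !(design$default_cond %in% default_conditions())
  if (any(bad))
    stop("invalid trials at rows: ", paste(utils::head(which(bad), 10), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.harm_design <- function(x, ...) {
  cat("Harm-allocation design: ", nrow(x), " trials (",
      length(unique(x$pair_id)), " pairs x ",
      length(unique(x$default_cond)), " default conditions)\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
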