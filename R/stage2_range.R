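# Stage-2 classifier: explicit CIELAB colour ranges separating red from
# light red tongue clusters, with a luminance fallback. The default box
# constraints are
#   red:       L* < 56,  32 <= a* <= 39,  6 <= b* <= 10
#   light red: L* >= 56, 23 <= a* <= 27, 15 <= b* <= 19
# A cluster colour outside both boxes (the ranges leave gaps in a*/b*) is
# resolved by luminance alone: L* below the threshold reads red, otherwise
# light red. 56 is the only luminance boundary the ranges define, so it also
# serves as the fallback threshold.

#' Colour-range rule set for red versus light red
#'
#' Builds the stage-2 rule set. Defaults encode the red colour range derived
#' from clinically labelled cluster colours; all bounds are configurable so
#' practitioners can substitute ranges fitted to their own corpus
#' ([range_stats()] helps derive them).
#'
#' @param red named list with `L_max` (exclusive), `a_min`, `a_max`,
#'   `b_min`, `b_max` (inclusive).
#' @param light_red named list with `L_min` (inclusive), `a_min`, `a_max`,
#'   `b_min`, `b_max` (inclusive).
#' @param fallback_L luminance threshold used when a colour matches neither
#'   box: `L* <` threshold reads red, else light red.
#' @return Object of class `range_rules`.
#' @export
range_rules <- function(red = list(L_max = 56, a_min = 32, a_max = 39,
                                   b_min = 6, b_max = 10),
                        light_red = list(L_min = 56, a_min = 23, a_max = 27,
                                         b_min = 15, b_max = 19),
                        fallback_L = 56) {
  for (box in list(red, light_red)) {
    if (box$a_min > box$a_max || box$b_min > box$b_max) {
      stop("invalid rule set: a/b range bounds out of order")
    }
  }
  stopifnot(is.finite(fallback_L), is.finite(red$L_max),
            is.finite(light_red$L_min))
  structure(list(red = red, light_red = light_red, fallback_L = fallback_L),
            class = "range_rules")
}

#' @export
print.range_rules <- function(x, ...) {
  cat(sprintf("<range_rules> red: L* < %g, %g <= a* <= %g, %g <= b* <= %g\n",
              x$red$L_max, x$red$a_min, x$red$a_max, x$red$b_min, x$red$b_max))
  cat(sprintf("        light red: L* >= %g, %g <= a* <= %g, %g <= b* <= %g\n",
              x$light_red$L_min, x$light_red$a_min, x$light_red$a_max,
              x$light_red$b_min, x$light_red$b_max))
  cat(sprintf("       fallback: L* < %g -> red, else light red\n",
              x$fallback_L))
  invisible(x)
}

.as_lab_matrix <- function(color) {
  m <- rbind(color)
  if (ncol(m) != 3L) stop("Lab colours must have 3 components (L, a, b)")
  if (anyNA(m) || any(!is.finite(m))) stop("Lab colour must be finite")
  dimnames(m) <- NULL
  m
}

#' Classify a cluster colour as red or light red
#'
#' Applies the full colour-range cascade to the mean Lab colour of the
#' red/light-red identifier cluster: a colour inside the red box is `red`;
#' otherwise, inside the light-red box, `light_red`; otherwise the luminance
#' fallback decides (`L* < fallback_L` means red). The red box requires
#' `L* < 56` and the light-red box `L* >= 56`, so the boxes are disjoint and
#' the rule is total: every finite Lab point receives exactly one label.
#'
#' @param color length-3 Lab vector or `n x 3` matrix of colours.
#' @param rules a [range_rules()] object.
#' @return Character label(s) in `red` / `light_red`, with attribute
#'   `rule_path` recording which branch fired (`"red_box"`,
#'   `"light_red_box"` or `"fallback_L"`).
#' @examples
#' classify_range(c(50, 35, 8))  # red, via the full-range box
#' classify_range(c(60, 25, 17)) # light red
#' classify_range(c(50, 25, 17)) # red, via the luminance fallback
#' @export
classify_range <- function(color, rules = range_rules()) {
  m <- .as_lab_matrix(color)
  L <- m[, 1]; a <- m[, 2]; b <- m[, 3]
  r <- rules$red; lr <- rules$light_red
  in_red <- L < r$L_max & a >= r$a_min & a <= r$a_max &
    b >= r$b_min & b <= r$b_max
  in_light <- L >= lr$L_min & a >= lr$a_min & a <= lr$a_max &
    b >= lr$b_min & b <= lr$b_max
  label <- ifelse(in_red, "red",
                  ifelse(in_light, "light_red",
                         ifelse(L < rules$fallback_L, "red", "light_red")))
  path <- ifelse(in_red, "red_box",
                 ifelse(in_light, "light_red_box", "fallback_L"))
  structure(label, rule_path = path)
}

#' Chromatic-attribute-only classification (ablation)
#'
#' Classifies using only the `a*`/`b*` chromatic ranges, ignoring luminance
#' entirely — the ablation that shows why luminance is needed: red and light
#' red overlap chromatically, so many colours fall in neither box and the
#' rule must abstain.
#'
#' @inheritParams classify_range
#' @return Character label(s) in `red` / `light_red` / `abstain`.
#' @export
chromatic_only_classify <- function(color, rules = range_rules()) {
  m <- .as_lab_matrix(color)
  a <- m[, 2]; b <- m[, 3]
  r <- rules$red; lr <- rules$light_red
  in_red <- a >= r$a_min & a <= r$a_max & b >= r$b_min & b <= r$b_max
  in_light <- a >= lr$a_min & a <= lr$a_max & b >= lr$b_min & b <= lr$b_max
  ifelse(in_red & !in_light, "red",
         ifelse(in_light & !in_red, "light_red", "abstain"))
}

#' Save / load a rule set as YAML
#'
#' Round-trips a [range_rules()] object through a human-editable YAML file.
#'
#' @param rules a `range_rules` object.
#' @param path file path.
#' @return `write_range_rules`: `path` invisibly; `read_range_rules`: a
#'   `range_rules` object.
#' @export
write_range_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' @rdname write_range_rules
#' @export
read_range_rules <- function(path) {
  x <- yaml::read_yaml(path)
  range_rules(red = x$red, light_red = x$light_red,
              fallback_L = x$fallback_L)
}

#' Per-class colour statistics for deriving ranges
#'
#' Utility for practitioners re-deriving colour ranges from their own
#' labelled corpus: per class, the min, max, mean and chosen percentiles of
#' each Lab channel over cluster colours.
#'
#' @param colors `n x 3` matrix of cluster mean colours.
#' @param labels class label per row.
#' @param probs percentile probabilities.
#' @return Data frame with one row per (class, channel).
#' @export
range_stats <- function(colors, labels, probs = c(0.05, 0.5, 0.95)) {
  colors <- .as_lab_matrix(colors)
  chans <- c("L", "a", "b")
  out <- do.call(rbind, lapply(split(seq_along(labels), labels), function(idx) {
    do.call(rbind, lapply(1:3, function(j) {
      v <- colors[idx, j]
      q <- stats::quantile(v, probs)
      data.frame(label = labels[idx[1]], channel = chans[j],
                 min = min(v), max = max(v), mean = mean(v),
                 t(stats::setNames(q, paste0("p", probs * 100))))
    }))
  }))
  rownames(out) <- NULL
  out
}
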