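# Independent oracles used across tests. These deliberately share no code
# with the package internals they check.

# Kahan compensated summation
kahan_sum <- function(v) {
  s <- 0; comp <- 0
  for (x in v) {
    y <- x - comp
    t <- s + y
    comp <- (t - s) - y
    s <- t
  }
  s
}

# linear-model oracle: term-by-term products summed in a shuffled order with
# compensated arithmetic
oracle_math_score <- function(params, coefs, order_seed = 1L) {
  fields <- setdiff(names(coefs), "intercept")
  x <- vapply(fields, function(f) {
    v <- params[[f]]
    if (is.character(v)) as.numeric(material_code(v)) else as.numeric(v)
  }, numeric(1L))
  terms <- c(coefs[["intercept"]], unname(coefs[fields] * x))
  set.seed(order_seed)
  kahan_sum(sample(terms))
}

# exhaustive between-class variance scan over every cut point of a histogram
oracle_otsu <- function(hist) {
  keep <- hist$count > 0
  v <- hist$mid[keep]; n <- hist$count[keep]
  stopifnot(length(v) >= 2L)
  w <- n / sum(n)
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(length(v) - 1L)) {
    lo <- seq_len(k); hi <- seq.int(k + 1L, length(v))
    w0 <- sum(w[lo]); w1 <- sum(w[hi])
    mu0 <- sum(w[lo] * v[lo]) / w0
    mu1 <- sum(w[hi] * v[hi]) / w1
    b <- w0 * w1 * (mu0 - mu1)^2
    if (b > best) { best <- b; best_k <- k }
  }
  (v[best_k] + v[best_k + 1L]) / 2
}

# 4-connected component labelling by explicit flood fill
oracle_label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start_i in seq_len(nrow(mask))) for (start_j in seq_len(ncol(mask))) {
    if (!mask[start_i, start_j] || lab[start_i, start_j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(start_i, start_j))
    lab[start_i, start_j] <- nxt
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1L] >= 1L && q[1L] <= nrow(mask) && q[2L] >= 1L &&
            q[2L] <= ncol(mask) && mask[q[1L], q[2L]] &&
            lab[q[1L], q[2L]] == 0L) {
          lab[q[1L], q[2L]] <- nxt
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# direct per-bin tally of values into histogram bins
oracle_bin_tally <- function(values, breaks) {
  counts <- numeric(length(breaks) - 1L)
  for (v in values) {
    for (b in seq_len(length(counts))) {
      upper_closed <- b == length(counts)
      if (v >= breaks[b] && (v < breaks[b + 1L] ||
                             (upper_closed && v <= breaks[b + 1L]))) {
        counts[b] <- counts[b] + 1
        break
      }
    }
  }
  counts
}

# a small valid parameter record with every continuous field zero
zero_params <- function(filter = "rhodium", anode = "rhodium") {
  imaging_parameters(0, 0, 0, 0, 0, 0, 0, 0, 0, filter, anode)
}

random_params <- function() {
  imaging_parameters(
    preexposure_dose = runif(1, 0, 10000),
    preexposure_thickness = runif(1, 0, 100),
    radiation_dose = runif(1, 0, 2000),
    preexposure_kvp = runif(1, 20, 35),
    anatomical_mean_intensity = runif(1, 0, 5000),
    thresh = runif(1, 0, 4000),
    final_exposure_thickness = runif(1, 0, 100),
    compression_force = runif(1, 0, 300),
    detector_sensitivity = runif(1, 0, 0.01),
    filter_material = sample(c("molybdenum", "rhodium"), 1),
    anode_material = sample(c("molybdenum", "rhodium"), 1))
}
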