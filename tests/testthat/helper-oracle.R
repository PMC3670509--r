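# Independent single-expression oracle for the body-fat battery: one
# straight-line evaluator per method, written directly from the published
# coefficient tables, sharing no code with the package implementation.

oracle_percent_fat <- function(s, method) {
  male <- s$sex == "male"
  s4 <- s$biceps + s$triceps + s$suprailiac + s$subscapular
  ts <- s$triceps + s$subscapular
  siri <- function(D) (4.95 / D - 4.50) * 100
  switch(method,
    EQ1 = {
      ay <- floor(s$age)
      if (ay < 15 || ay > 18) return(NA_real_)
      D <- if (male) {
        if (ay <= 16) 1.1533 - 0.0643 * log10(s4) else 1.1620 - 0.0630 * log10(s4)
      } else {
        if (ay <= 16) 1.1369 - 0.0598 * log10(s4) else 1.1549 - 0.0678 * log10(s4)
      }
      siri(D)
    },
    EQ2 = 1.35 * ts - 0.012 * ts^2 - (if (male) 4.4 else 2.4),
    EQ3 = if (male) 0.735 * (s$triceps + s$calf) + 1.0
          else 0.610 * (s$triceps + s$calf) + 5.1,
    EQ4 = {
      if (ts > 35) {
        if (male) 0.783 * ts + 1.6 else 0.546 * ts + 9.7
      } else if (male) {
        icpt <- if (s$race == "nonwhite") {
          c(prepubescent = -3.5, pubescent = -5.2, postpubescent = -6.8)
        } else {
          c(prepubescent = -1.7, pubescent = -3.4, postpubescent = -5.5)
        }
        1.21 * ts - 0.008 * ts^2 + icpt[[s$maturation]]
      } else {
        1.33 * ts - 0.013 * ts^2 - 2.5
      }
    },
    EQ5 = {
      a <- s$age
      if (male) {
        D <- (1.1315 + 0.0018 * (a - 2)) - (0.0719 - 0.0006 * (a - 2)) * log10(s4)
        (562 - 4.2 * (a - 2)) / D - (525 - 4.7 * (a - 2))
      } else {
        D <- (1.1350 + 0.0031 * (a - 10)) - (0.0719 - 0.0003 * (a - 2)) * log10(s4)
        (553 - 7.3 * (a - 10)) / D - (514 - 8.0 * (a - 10))
      }
    },
    EQ6 = {
      ht2r <- s$height^2 / s$resistance
      ffm <- if (male) {
        0.646 * s$weight - 0.116 * s$calf - 0.375 * s$midaxillary +
          0.475 * (s$brachial_perimeter - pi * s$triceps / 10) +
          0.156 * ht2r - 2.932
      } else {
        0.682 * s$weight - 0.185 * s$calf - 0.244 * s$triceps -
          0.202 * s$subscapular + 0.182 * ht2r + 4.338
      }
      100 * (s$weight - ffm) / s$weight
    },
    EQ7 = if (male) 18.88 * log10(s4) - 15.58 else 39.02 * log10(s4) - 43.49,
    EQ8 = {
      b <- s$weight / (s$height / 100)^2
      sx <- as.numeric(male)
      if (floor(s$age) <= 15) 1.51 * b - 0.70 * s$age - 3.6 * sx + 1.4
      else 1.2 * b + 0.23 * s$age - 10.8 * sx - 5.4
    },
    EQ9 = {
      ffm <- 0.61 * s$height^2 / s$resistance + 0.25 * s$weight + 1.31
      100 * (s$weight - ffm) / s$weight
    },
    EQ10 = {
      f <- if (male && s$race == "white") {
        0.534 * s$weight - 1.59 * s$age + 3.03
      } else if (male) {
        0.594 * s$weight - 0.381 * s$height + 36.0
      } else if (s$race == "white") {
        0.642 * s$weight - 0.120 * s$height - 0.606 * s$age + 8.98
      } else {
        0.653 * s$weight - 0.163 * s$height - 0.298 * s$age + 10.7
      }
      100 * f / s$weight
    },
    BIA1 = oracle_percent_fat(s, "EQ9"),
    BIA2 = s$bia2_percent_fat
  )
}

oracle_battery <- function(subjects, methods = bf_methods()) {
  out <- expand.grid(subject_id = subjects$subject_id, method = methods,
                     stringsAsFactors = FALSE)
  out$percent_fat <- mapply(function(id, m) {
    oracle_percent_fat(as.list(subjects[subjects$subject_id == id, ]), m)
  }, out$subject_id, out$method)
  out
}
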