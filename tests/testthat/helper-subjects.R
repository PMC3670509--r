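# Fixture builders used across the suite.

make_subject <- function(subject_id = "S1", sex = "male", age = 16.5,
                         race = "white", maturation = "postpubescent",
                         weight = 60, height = 170,
                         biceps = 6, triceps = 10, subscapular = 10,
                         suprailiac = 8, midaxillary = 8, calf = 10,
                         brachial_perimeter = 26, resistance = 500,
                         bia2_percent_fat = 18, group = "eutrophic") {
  tibble::tibble(
    subject_id = subject_id, sex = sex, age = age, race = race,
    maturation = maturation, weight = weight, height = height,
    biceps = biceps, triceps = triceps, subscapular = subscapular,
    suprailiac = suprailiac, midaxillary = midaxillary, calf = calf,
    brachial_perimeter = brachial_perimeter, resistance = resistance,
    bia2_percent_fat = bia2_percent_fat, group = group
  )
}

random_subjects <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("R%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 15, 18.99),
    race = sample(c("white", "nonwhite"), n, replace = TRUE),
    maturation = sample(c("prepubescent", "pubescent", "postpubescent"),
                        n, replace = TRUE),
    weight = runif(n, 45, 100),
    height = runif(n, 150, 192),
    biceps = runif(n, 4, 40),
    triceps = runif(n, 4, 40),
    subscapular = runif(n, 4, 40),
    suprailiac = runif(n, 4, 40),
    midaxillary = runif(n, 4, 40),
    calf = runif(n, 4, 40),
    brachial_perimeter = runif(n, 20, 36),
    resistance = runif(n, 380, 750),
    bia2_percent_fat = runif(n, 5, 45),
    group = sample(c("eutrophic", "overweight"), n, replace = TRUE)
  ))
}
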