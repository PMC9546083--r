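No datasets are bundled.

The nine-trial calcium-supplementation example (body weight at baseline and
follow-up, calcium supplements vs placebo/no treatment) that motivates the
acceptance test "worked-example reproduction" is distributed with the
original interactive analysis tool's repository and is not redistributed
here. To run that test, obtain the trial-level summary data, arrange them in
the canonical column layout (see ?meta_dataset or write_template()) and save
them as calcium.csv in this directory before installing the package.
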