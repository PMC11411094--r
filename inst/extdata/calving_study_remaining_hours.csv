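indicator,h021,h045,h057,h055,h058,h886
SMA,53.0,69.5,61.0,,42.5,44.5
MAD,56.0,76.0,66.0,43.0,47.5,63.5
MACD,53.5,72.0,62.0,42.5,43.5,59.5
RSI,56.0,72.0,62.0,,43.5,45.0
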