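name	record	start	end
5S	RNA5S	NA	NA
5.8S	RNA5-8S	NA	NA
28S	RNA28S-5prime	NA	NA
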