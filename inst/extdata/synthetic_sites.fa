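>synthetic_site_01
AAAACCCCGT
>synthetic_site_02
AAAACTCCAT
>synthetic_site_03
TAAACTCTAT
>synthetic_site_04
AACACCCGAT
>synthetic_site_05
ATAACGCCCT
>synthetic_site_06
TAAACTCCAT
>synthetic_site_07
CAAACTTCAT
>synthetic_site_08
AAAACTCCAT
>synthetic_site_09
AAAACTCTAA
>synthetic_site_10
ACAACTCCAT
>synthetic_site_11
TAAACTCCAT
>synthetic_site_12
ACATCTCCAG
>synthetic_site_13
CGATCTCCAT
>synthetic_site_14
TAAACTCCAT
>synthetic_site_15
ACAACTCCAT
>synthetic_site_16
AAAACTCCAT
>synthetic_site_17
AAAACTCCAT
>synthetic_site_18
TAAACCCCGT
>synthetic_site_19
AAAACTCCAT
>synthetic_site_20
AAAACTCCAT
>synthetic_site_21
AAAATTCCAT
>synthetic_site_22
AAAAATCCCT
>synthetic_site_23
AAATCTCGAT
>synthetic_site_24
AAACCTCCAC
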