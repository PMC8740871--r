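names:
- Tr
- Gl
- 'N'
- Prn
- Sn
- Ls
- Sto
- Li
- Gn
- Zy_l
- Zy_r
- Go_l
- Go_r
- Ch_l
- Ch_r
- Al_l
- Al_r
- Ex_l
- Ex_r
- En_l
- En_r
- Ps_l
- Ps_r
- Pi_l
- Pi_r
- Pu_l
- Pu_r
- EbM_l
- EbM_r
- EbL_l
- EbL_r
- Chk_l
- Chk_r
- Tmp_l
- Tmp_r
- Nst_l
- Nst_r
- out1_l
- out2_l
- out3_l
- out4_l
- out5_l
- out6_l
- out7_l
- out8_l
- out9_l
- out10_l
- out1_r
- out2_r
- out3_r
- out4_r
- out5_r
- out6_r
- out7_r
- out8_r
- out9_r
- out10_r
- brow1_l
- brow2_l
- brow3_l
- brow1_r
- brow2_r
- brow3_r
- lipU1_l
- lipU2_l
- lipU1_r
- lipU2_r
- lipL1_l
- lipL2_l
- lipL1_r
- lipL2_r
role:
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- fixed
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
- semilandmark
pairs:
- - 10
  - 11
- - 12
  - 13
- - 14
  - 15
- - 16
  - 17
- - 18
  - 19
- - 20
  - 21
- - 22
  - 23
- - 24
  - 25
- - 26
  - 27
- - 28
  - 29
- - 30
  - 31
- - 32
  - 33
- - 34
  - 35
- - 36
  - 37
- - 38
  - 48
- - 39
  - 49
- - 40
  - 50
- - 41
  - 51
- - 42
  - 52
- - 43
  - 53
- - 44
  - 54
- - 45
  - 55
- - 46
  - 56
- - 47
  - 57
- - 58
  - 61
- - 59
  - 62
- - 60
  - 63
- - 64
  - 66
- - 65
  - 67
- - 68
  - 70
- - 69
  - 71
midline:
- 1
- 2
- 3
- 4
- 5
- 6
- 7
- 8
- 9
sliders:
- - 1
  - 38
  - 39
- - 38
  - 39
  - 40
- - 39
  - 40
  - 41
- - 40
  - 41
  - 42
- - 41
  - 42
  - 43
- - 42
  - 43
  - 44
- - 43
  - 44
  - 45
- - 44
  - 45
  - 46
- - 45
  - 46
  - 47
- - 46
  - 47
  - 9
- - 1
  - 48
  - 49
- - 48
  - 49
  - 50
- - 49
  - 50
  - 51
- - 50
  - 51
  - 52
- - 51
  - 52
  - 53
- - 52
  - 53
  - 54
- - 53
  - 54
  - 55
- - 54
  - 55
  - 56
- - 55
  - 56
  - 57
- - 56
  - 57
  - 9
- - 28
  - 58
  - 59
- - 58
  - 59
  - 60
- - 59
  - 60
  - 30
- - 29
  - 61
  - 62
- - 61
  - 62
  - 63
- - 62
  - 63
  - 31
- - 14
  - 64
  - 65
- - 64
  - 65
  - 6
- - 15
  - 66
  - 67
- - 66
  - 67
  - 6
- - 14
  - 68
  - 69
- - 68
  - 69
  - 8
- - 15
  - 70
  - 71
- - 70
  - 71
  - 8
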